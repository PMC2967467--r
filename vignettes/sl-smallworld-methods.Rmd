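---
title: "Synchronization likelihood and small-world graph analysis: methods"
author: "SLgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization likelihood and small-world graph analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SLgraph)
```

# What the package computes

SLgraph analyses whole-brain functional connectivity from regional BOLD
time-series.  Its pipeline has four stages:

1. **Synchronization likelihood (SL).**  For every pair of regional
   series, SL estimates the probability that a recurrence of a dynamical
   pattern in one series coincides in time with a recurrence in the
   other.  Because it works on delay-embedded state vectors and distance
   ranks, it is sensitive to linear *and* nonlinear coupling, and
   invariant to affine rescaling of each series.  Under independence SL
   fluctuates around the reference probability `pref`; for identical
   series it is exactly 1.
2. **Binary graphs.**  The R × R matrix of pairwise SL values is
   binarized either at a fixed threshold T (edge iff SL > T) or at a
   fixed mean degree K (keep the round(N·K/2) strongest pairs).  Fixed-K
   graphs equalize edge counts across subjects, so group differences in
   the descriptors reflect topology, not overall synchronization level.
3. **Small-world descriptors.**  The clustering coefficient C (mean
   per-vertex fraction of connected neighbour pairs) measures local
   segregation; the harmonic characteristic path length
   L = nPairs / Σ 1/d measures global integration, with disconnected
   pairs contributing zero inverse distance.  Both are normalized by
   their means over degree-preserving rewired surrogate networks:
   γ = C/C₋s and λ = L/L₋s.  λ → 1 indicates a topology that is random
   conditional on its degree sequence.
4. **Group statistics.**  Per-level pooled two-sample t statistics are
   combined across the T or K grid by a cluster-based permutation test
   (max-|cluster-sum| statistic under group relabelling), and regional
   differences are mapped by pairwise two-tailed t tests at an
   uncorrected α, read at the granularity of lobe blocks.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lag` | 1 | samples | delay-embedding lag |
| `dim` | 6 | – | embedding dimension |
| `theiler` | 6 | samples | exclusion of temporally adjacent candidates |
| `pref` | 0.01 | probability | per-timepoint recurrence fraction |
| T grid | 0.01–0.05 by 0.01 | SL units | threshold sweep |
| K grid | 5–15 by 1 | edges/vertex | fixed-degree sweep |
| surrogates | 50 | – | rewired networks per graph |
| permutations | 5000 | – | Monte-Carlo repartitions |
| α (regional map) | 0.05 | – | uncorrected pairwise level |

The embedding defaults suit ~200-volume resting-state series with a TR
of ~2.85 s; with far shorter series the number of embedded vectors
M = Tn − (dim − 1)·lag, and hence the recurrence candidate pool,
shrinks and SL becomes noisy.  The sparse-graph regime N > K > ln N > 1
keeps comparable random graphs connected; `graphFromDegree()` warns
outside it.

# Numerical conventions

* **Critical distance by rank.**  The per-timepoint radius ε is the
  distance of the r-th nearest candidate, r = ⌈pref · nCandidates⌉,
  which controls the recurrence fraction exactly and deterministically;
  recurrence comparisons use ≤ ε so tied distances all count.
* **Theiler window.**  Candidates with |i − j| ≤ `theiler` are excluded
  on both sides of i; boundary timepoints simply have fewer candidates
  and the same rank rule.
* **Degenerate input.**  A constant region series has no recurrence
  geometry; `slMatrix()` fails fast naming the region.
* **Symmetry.**  The two conditional directions (recurrences of x found
  in y and vice versa) are averaged, so `slPair(x, y) == slPair(y, x)`
  to machine precision and the diagonal of a `SyncMatrix` is fixed at 1
  and excluded from every statistic.
* **Fixed-K ties.**  Edge selection sorts by descending SL, then
  ascending (i, j); the rule is arbitrary but deterministic, which the
  reproducibility guarantees require.
* **Harmonic L.**  Graphs with at least one edge always have finite L
  under the inverse-distance convention; a fully edgeless graph is
  reported as `Inf` rather than given a number.  Surrogate means L₋s
  average the surrogates with finite L and report the infinite count
  separately.
* **Cluster test.**  Supra-threshold cuts sit at the 2.5th/97.5th
  quantiles of the t distribution with n₁ + n₂ − 2 df.  The two-sided
  statistic is the maximum absolute cluster sum; the permutation null
  uses the add-one convention p = (#{perm ≥ obs} + 1)/(B + 1), and
  switches to exhaustive enumeration of all repartitions whenever there
  are at most 20000 of them.  Pooled-variance t is the default (df
  matches the classic convention); Welch is available as an option.
* **Seeding.**  Every stochastic step takes an explicit seed and leaves
  the global RNG untouched (`withr::with_seed`); per-subject simulation
  streams are derived as `seed + 101·i`, and per-(subject, level)
  surrogate streams as documented in `cohortMetrics()`.

# The synthetic cohort generator

No imaging data ship with the package; a latent-factor generator stands
in for a two-group resting-state cohort (defaults: 21 controls, 18
patients, 116 regions × 200 volumes).  Each region's series is

y_r = Σ_b w(block(r), b) · z_b + g₀ · z_global + σ ε_r,

moving-average smoothed over 3 samples to mimic slow BOLD fluctuations.
The block-pair loading matrix `w` gives direct, monotone control of
block-pairwise synchrony.  The strong global signal (g₀ = 0.7) mirrors
the shared physiological component of resting BOLD and puts the
whole-brain mean SL near the empirically typical ~0.09; σ = 0.35 sets
realistic pairwise correlations, to which SL responds nonlinearly
(roughly: SL ≈ 0.02 at ρ = 0.45, ≈ 0.06 at ρ = 0.75, ≈ 0.18 at
ρ = 0.9).

The healthy baseline couples regions strongly within blocks (0.45;
frontal 0.55, which keeps the large frontal block near-saturated in
both groups) with weak generic background (0.15) and three elevated
long-range axes (fronto-parieto-occipital 0.30, left-temporal–posterior
0.25, right-temporal–frontal 0.20).

The disease effect adds per-block deltas for the patient group:
frontal increases (+0.10 within frontal, +0.10 right-temporal–frontal)
and generalized posterior decreases (−0.35 within parieto-occipital,
−0.20 fronto-parieto-occipital, −0.20 within left-temporal, −0.15
left-temporal–posterior).  The design rationale: purely between-block
decreases make patient networks *more* modular (fewer inter-cluster
shortcuts), which raises λ — the opposite of the disease phenotype of
interest.  The documented phenotype is a *randomization*: posterior
synchronization decreases are generalized, i.e. they erode the
posterior module's internal coherence.  With the default deltas the
posterior block's coherence collapses towards the generic background,
so at fixed K its edges are placed nearly at random while the frontal
core persists — a mild topological randomization that lowers both L and
λ in patients, with the whole-brain mean S essentially unchanged.  The
magnitudes were fixed once, during generator design, so that this
mechanism operates clearly at the scaled study conditions below.

A density caveat discovered during design: at very sparse K the
synthetic patient networks fragment instead (near-isolated posterior
vertices are penalized by the harmonic path length), and λ moves the
other way.  The λ comparison is therefore made at K = 10 — the same
working point as the full-size summary table — which sits in the
randomization regime.

# Problem sizes used by the test-suite

The checks that run the full pipeline repeatedly use a scaled study
design chosen to keep the whole suite within a desktop budget while
preserving every structural feature: 40 regions subset from the
bundled registry with the full lobe-block structure (14 frontal, 10
parieto-occipital, 4 + 4 temporal, 8 subcortical), 8 + 8 subjects, 200
timepoints, λ evaluated at K = 10 with 20 surrogates, 20 seeded
replicates.  Statistical calibration of the cluster permutation test
runs 200 null replicates at the full study size (21 vs 18 subjects, 11
levels) on directly simulated per-subject metric values, which is the
quantity the test actually consumes.  Oracle-equivalence checks
(naive SL double loop, exhaustive triangle counting, Floyd–Warshall,
exhaustive repartition) run at small sizes where brute force is exact.

# What the generator does and does not emulate

It reproduces: two groups with realistic global synchronization, block
structure visible in the SL matrices, BOLD-like smoothness, a disease
effect with the documented regional pattern and the corrected-path-
length signature, and full determinism.  It does not model hemodynamics
(no balloon model), head motion, scanner drift, physical distance
between regions, spatially graded connectivity within blocks, or
volumetric images.  Passing tests therefore demonstrate that the
pipeline detects the intended effects in a controlled generative model
— not that it would detect them in any particular real data set, where
effect sizes, artifacts and confounds differ.

# Known limitations

* SL compresses differences among moderate correlations (its response
  to ρ is convex), so group contrasts in weakly coupled region pairs
  need larger cohorts than the same contrast at high coupling.
* The γ of the synthetic cohorts (~1.4–2 at the scaled size) is below
  values typical of real whole-brain networks (~3–4.5): the generator's
  blocks are internally unstructured, so clustering beyond the block
  scale is absent.  The synthetic patients also show *elevated* γ (the
  denser frontal core is cliquish), whereas real patient cohorts
  typically show no γ difference; only the λ direction is treated as a
  recovery target.  Direction checks on λ are unaffected.
* The harmonic-L convention keeps L finite for any non-empty graph but
  makes near-isolated vertices influential at very sparse K; results
  near the connectivity boundary K ≈ ln N should be read with care.
* The fixed-K tie-break and the surrogate swap budget (10·|E| attempts)
  are conventions; both are documented and isolated behind single
  functions.
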