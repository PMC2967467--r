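Package: SLgraph
Title: Synchronization Likelihood and Small-World Graph Analysis of
    Regional Brain Time Series
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes synchronization likelihood (SL), a measure of linear
    and nonlinear coupling between regional BOLD time-series, builds binary
    functional-connectivity graphs at fixed synchronization threshold T or
    fixed mean degree K, and characterizes them with the clustering
    coefficient C and the harmonic characteristic path length L, normalized
    by degree-preserving rewired surrogate networks (gamma = C/C-s,
    lambda = L/L-s).  Group differences across threshold levels are
    assessed with per-level two-sample t-tests and a cluster-based
    permutation test, and regional synchronization differences are mapped
    pairwise.  A latent-factor cohort simulator generates two-group
    region-by-time data with block-structured coupling, BOLD-like temporal
    autocorrelation, and a configurable disease effect, so the full
    pipeline is testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, TimeCourse, StatisticalMethod
RoxygenNote: 7.3.3
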