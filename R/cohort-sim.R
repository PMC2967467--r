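# Synthetic two-group cohorts: latent-factor Gaussian model with one
# latent signal per lobe block plus one global signal, moving-average
# smoothing for BOLD-like autocorrelation, and a block-pairwise disease
# effect added to the patient group's loadings.

.blockOrder <- c("frontal", "temporal-L", "temporal-R",
                 "parieto-occipital", "subcortical", "cerebellar")

#' Default block-pair latent loadings
#'
#' The healthy baseline: within-block coupling is strong (0.45; 0.55 for
#' the large frontal block, which keeps it near-saturated in both groups);
#' generic between-block coupling is weak (0.15).  Two long-range axes
#' are strengthened so that the disease effect has room to act on them:
#' the fronto-parieto-occipital axis (0.30) and the left-temporal-
#' posterior axis (0.25); the right-temporal-frontal axis starts at 0.20.
#'
#' @return Symmetric 6 x 6 numeric matrix over the lobe blocks.
#' @seealso [defaultAdEffect()], [cohortConfig()]
#' @export
defaultBaseCoupling <- function() {
  b <- .blockOrder
  m <- matrix(0.15, 6, 6, dimnames = list(b, b))
  diag(m) <- 0.45
  m["frontal", "frontal"] <- 0.55
  m["frontal", "parieto-occipital"] <- m["parieto-occipital", "frontal"] <- 0.30
  m["temporal-L", "parieto-occipital"] <- m["parieto-occipital", "temporal-L"] <- 0.25
  m["temporal-R", "frontal"] <- m["frontal", "temporal-R"] <- 0.20
  m
}

#' Default disease (AD-like) coupling deltas
#'
#' Additive per-block-pair deltas applied to the patient group's
#' loadings: increases of frontal coupling (+0.10 frontal-frontal, +0.10
#' right-temporal-frontal) and generalized decreases centred on the
#' posterior cortex (-0.35 within parieto-occipital, -0.20
#' frontal-parieto-occipital, -0.20 within left-temporal, -0.15
#' left-temporal-posterior).  The posterior module's coherence collapses
#' towards the generic background while the frontal core persists, so
#' patient networks place their posterior edges near-randomly — a mild
#' topological randomization that lowers the corrected path length, the
#' disease signature the generator is built to emulate.
#'
#' @return Symmetric 6 x 6 numeric matrix over the lobe blocks.
#' @seealso [defaultBaseCoupling()], [cohortConfig()]
#' @export
defaultAdEffect <- function() {
  b <- .blockOrder
  m <- matrix(0, 6, 6, dimnames = list(b, b))
  m["frontal", "frontal"] <- 0.10
  m["parieto-occipital", "parieto-occipital"] <- -0.35
  m["temporal-L", "temporal-L"] <- -0.20
  m["frontal", "parieto-occipital"] <- m["parieto-occipital", "frontal"] <- -0.20
  m["temporal-L", "parieto-occipital"] <- m["parieto-occipital", "temporal-L"] <- -0.15
  m["temporal-R", "frontal"] <- m["frontal", "temporal-R"] <- 0.10
  m
}

#' Construct a cohort configuration
#'
#' The regions and their lobe blocks are taken from a ROI registry (the
#' bundled 116-region atlas by default; see [aalRegistry()] and
#' [subsetRegistry()] for scaled-down designs).  Defaults mirror a
#' resting-state study design: 21 controls, 18 patients, 200 volumes at
#' TR 2.85 s.
#'
#' @param nControl,nPatient group sizes.
#' @param nTimepoints volumes per subject.
#' @param registry data.frame with columns `region` and `block`.
#' @param baseCoupling,adEffect symmetric block-pair matrices; see
#'   [defaultBaseCoupling()] and [defaultAdEffect()].
#' @param noiseSd innovation noise SD (default 0.35).
#' @param globalLoading loading of the shared global signal (default 0.7);
#'   a strong global component mirrors the shared physiological signal of
#'   resting-state BOLD and sets the whole-brain mean synchronization near
#'   the empirical ~0.09.
#' @param smoothWindow odd moving-average width in samples (default 3).
#' @param trSeconds repetition time in seconds (default 2.85).
#' @param seed integer master seed.
#' @return A [CohortConfig-class] object.
#' @export
cohortConfig <- function(nControl = 21L, nPatient = 18L,
                         nTimepoints = 200L, registry = aalRegistry(),
                         baseCoupling = defaultBaseCoupling(),
                         adEffect = defaultAdEffect(),
                         noiseSd = 0.35, globalLoading = 0.7,
                         smoothWindow = 3L, trSeconds = 2.85,
                         seed = 1L) {
  blockMap <- stats::setNames(as.character(registry$block),
                              as.character(registry$region))
  new("CohortConfig", nControl = as.integer(nControl),
      nPatient = as.integer(nPatient),
      nTimepoints = as.integer(nTimepoints), blockMap = blockMap,
      baseCoupling = baseCoupling, adEffect = adEffect,
      noiseSd = as.numeric(noiseSd),
      globalLoading = as.numeric(globalLoading),
      smoothWindow = as.integer(smoothWindow),
      trSeconds = as.numeric(trSeconds), seed = as.integer(seed))
}

# Moving-average smoothing of each row; the series is generated with
# floor(w/2) extra samples on each side so the smoothed series has full
# length with no edge NA.
.smoothRows <- function(m, w) {
  if (w <= 1L) return(m)
  h <- w %/% 2L
  sm <- t(apply(m, 1L, function(r)
    stats::filter(r, rep(1 / w, w), sides = 2)))
  sm[, (h + 1L):(ncol(m) - h), drop = FALSE]
}

#' Simulate a two-group cohort of regional time-series
#'
#' Each region's series is a weighted sum of one latent Gaussian signal
#' per lobe block (weights = the row of the subject group's coupling
#' matrix for the region's block) plus a shared global signal and white
#' noise, then moving-average smoothed.  Patients use
#' `baseCoupling + adEffect` as loadings; controls use `baseCoupling`.
#' Subject i's stream is seeded with `seed + 101 * i`, so the cohort is
#' bit-reproducible and individual subjects can be regenerated in
#' isolation.
#'
#' @param config a [CohortConfig-class] object.
#' @return A list of `nControl + nPatient` [RegionalTimeSeries-class]
#'   objects (controls first), named by subject id.
#' @examples
#' reg <- subsetRegistry(aalRegistry(), c(frontal = 4,
#'   "parieto-occipital" = 4, subcortical = 3))
#' cfg <- cohortConfig(nControl = 2, nPatient = 2, nTimepoints = 60,
#'                     registry = reg, seed = 7)
#' cohort <- simulateCohort(cfg)
#' length(cohort)
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  blocks <- rownames(config@baseCoupling)
  regionBlock <- match(config@blockMap, blocks)
  nTotal <- config@nControl + config@nPatient
  groups <- rep(c("control", "patient"),
                c(config@nControl, config@nPatient))
  loadC <- config@baseCoupling
  loadP <- config@baseCoupling + config@adEffect
  h <- config@smoothWindow %/% 2L
  TnExt <- config@nTimepoints + 2L * h
  R <- length(config@blockMap)
  lapply(stats::setNames(seq_len(nTotal),
                         sprintf("sub%03d", seq_len(nTotal))),
         function(i) {
    load <- if (groups[i] == "control") loadC else loadP
    W <- cbind(load[regionBlock, , drop = FALSE],
               global = config@globalLoading)
    y <- withr::with_seed(config@seed + 101L * i, {
      latent <- matrix(stats::rnorm((length(blocks) + 1L) * TnExt),
                       length(blocks) + 1L, TnExt)
      noise <- matrix(stats::rnorm(R * TnExt, sd = config@noiseSd),
                      R, TnExt)
      W %*% latent + noise
    })
    y <- .smoothRows(y, config@smoothWindow)
    rownames(y) <- names(config@blockMap)
    regionalTimeSeries(sprintf("sub%03d", i), groups[i], y,
                       trSeconds = config@trSeconds)
  })
}

#' Unidirectionally coupled chaotic map pair
#'
#' A driver-response pair of logistic maps (a = 4, fully chaotic) for
#' validating the sensitivity of synchronization measures to generalized
#' coupling.  The driver evolves as x' = 4x(1-x) plus a small dynamical
#' noise; the response mixes its own logistic dynamics with the driver's
#' state: y' = (1-c) * 4y(1-y) + c * x'.  At c = 1 the response equals
#' the driver exactly; at c = 0 the two series are independent.
#'
#' @param coupling c in [0, 1].
#' @param n output series length (>= 50).
#' @param seed integer seed for initial conditions and driver noise.
#' @param noiseSd SD of the driver's dynamical noise (default 0.005).
#' @param transient number of initial iterations discarded (default 100).
#' @return A list with numeric vectors `driver` and `response` of
#'   length n.
#' @export
coupledMapPair <- function(coupling, n, seed, noiseSd = 0.005,
                           transient = 100L) {
  if (coupling < 0 || coupling > 1)
    stop("'coupling' must lie in [0, 1]")
  stopifnot(n >= 50L)
  withr::with_seed(as.integer(seed), {
    total <- n + transient
    eta <- stats::rnorm(total, sd = noiseSd)
    x <- numeric(total)
    y <- numeric(total)
    x[1] <- stats::runif(1, 0.05, 0.95)
    y[1] <- stats::runif(1, 0.05, 0.95)
    for (t in seq_len(total - 1L)) {
      x[t + 1L] <- min(max(4 * x[t] * (1 - x[t]) + eta[t], 1e-6), 1 - 1e-6)
      y[t + 1L] <- (1 - coupling) * 4 * y[t] * (1 - y[t]) +
        coupling * x[t + 1L]
    }
    list(driver = x[(transient + 1L):total],
         response = y[(transient + 1L):total])
  })
}
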