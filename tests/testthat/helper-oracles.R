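# Independent brute-force oracles and small fixture builders used across
# the test files.  These deliberately avoid the package's internal code
# paths (and igraph) wherever they serve as a cross-check.

# Naive O(M^2) synchronization likelihood, straight from the definition:
# explicit loops, per-i critical distances by full sort, both conditional
# directions averaged.
naiveSlPair <- function(x, y, p) {
  embed1 <- function(s) {
    M <- length(s) - (p@dim - 1L) * p@lag
    t(sapply(seq_len(M), function(i) s[i + (0:(p@dim - 1L)) * p@lag]))
  }
  Ex <- embed1(x)
  Ey <- embed1(y)
  M <- nrow(Ex)
  epsFor <- function(E, i) {
    d <- numeric(0)
    for (j in seq_len(M))
      if (abs(i - j) > p@theiler)
        d <- c(d, sqrt(sum((E[i, ] - E[j, ])^2)))
    sort(d)[max(1L, ceiling(p@pref * length(d)))]
  }
  acc <- 0
  for (i in seq_len(M)) {
    ex <- epsFor(Ex, i)
    ey <- epsFor(Ey, i)
    kx <- ky <- joint <- 0L
    for (j in seq_len(M)) {
      if (abs(i - j) <= p@theiler) next
      inx <- sqrt(sum((Ex[i, ] - Ex[j, ])^2)) <= ex
      iny <- sqrt(sum((Ey[i, ] - Ey[j, ])^2)) <= ey
      kx <- kx + inx
      ky <- ky + iny
      joint <- joint + (inx && iny)
    }
    acc <- acc + 0.5 * (joint / kx + joint / ky)
  }
  acc / M
}

adjacencyOf <- function(g) {
  n <- numVertices(g)
  a <- matrix(0L, n, n)
  e <- edgeMatrix(g)
  a[e] <- 1L
  a[e[, 2:1, drop = FALSE]] <- 1L
  a
}

# Clustering coefficient by exhaustive neighbor-pair enumeration.
bruteClustering <- function(g) {
  a <- adjacencyOf(g)
  n <- nrow(a)
  cv <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(a[v, ] == 1L)
    k <- length(nb)
    if (k < 2L) next
    links <- 0L
    for (ii in seq_len(k - 1L))
      for (jj in seq.int(ii + 1L, k))
        links <- links + a[nb[ii], nb[jj]]
    cv[v] <- links / (k * (k - 1L) / 2)
  }
  mean(cv)
}

# Harmonic path length via Floyd-Warshall all-pairs distances.
floydHarmonicL <- function(g) {
  a <- adjacencyOf(g)
  n <- nrow(a)
  if (sum(a) == 0L) return(Inf)
  d <- matrix(Inf, n, n)
  d[a == 1L] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  (n * (n - 1) / 2) / sum(inv)
}

# Synthetic symmetric synchronization matrix with Gaussian perturbations
# around a base level (for statistics tests that do not need real SL).
randomSyncMatrix <- function(n, seed, base = 0.5, sd = 0.05,
                             shift = NULL) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- base + stats::rnorm(n * (n - 1) / 2, sd = sd)
    if (!is.null(shift))
      m[upper.tri(m)] <- m[upper.tri(m)] + shift[upper.tri(shift)]
    m[upper.tri(m)] <- pmin(pmax(m[upper.tri(m)], 0), 1)
    m <- m + t(m)
    syncMatrix(m, labels = paste0("R", seq_len(n)))
  })
}

# The scaled two-group study design used by the heavier end-to-end
# checks: 40 regions keeping the full lobe-block structure, 8 + 8
# subjects, 200 timepoints, default coupling and disease effect.
scaledRegistry <- function() {
  subsetRegistry(aalRegistry(),
                 c(frontal = 14, "temporal-L" = 4, "temporal-R" = 4,
                   "parieto-occipital" = 10, subcortical = 8))
}

scaledConfig <- function(seed, nControl = 8L, nPatient = 8L,
                         adEffect = defaultAdEffect()) {
  cohortConfig(nControl = nControl, nPatient = nPatient,
               registry = scaledRegistry(), adEffect = adEffect,
               seed = seed)
}

quickSubject <- function(nRegions, nTimepoints, seed, id = "s1",
                         group = "control") {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(nRegions * nTimepoints), nRegions)
    rownames(m) <- paste0("R", seq_len(nRegions))
    regionalTimeSeries(id, group, m)
  })
}
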