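# Small-world descriptors: clustering coefficient C, harmonic path length
# L, degree-preserving rewired surrogates, and the surrogate-corrected
# ratios gamma = C/C-s and lambda = L/L-s.

#' Clustering coefficient
#'
#' Per-vertex clustering is the fraction of a vertex's neighbor pairs that
#' are themselves joined by an edge; vertices of degree < 2 contribute 0.
#' The global coefficient is the mean over all vertices.
#'
#' @param g a [BinaryGraph-class].
#' @return A list with `global` (the mean) and `local` (per-vertex values).
#' @examples
#' cc <- clusteringCoefficient(ringLattice(20, 4))
#' cc$global  # 0.5
#' @export
clusteringCoefficient <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  local <- igraph::transitivity(asIgraph(g), type = "local",
                                isolates = "zero")
  local[is.nan(local)] <- 0
  list(global = mean(local), local = local)
}

#' Harmonic characteristic path length
#'
#' L = nPairs / sum over vertex pairs of 1/d(i, j), with shortest-path
#' distances d in edges and 1/d = 0 for disconnected pairs.  Under this
#' harmonic rule L is finite for any graph with at least one edge; a fully
#' edgeless graph has no defined length and is reported as `Inf`.
#'
#' @param g a [BinaryGraph-class].
#' @return A single number >= 1, or `Inf` for an edgeless graph.
#' @examples
#' harmonicPathLength(binaryGraph(3, rbind(c(1, 2), c(2, 3))))  # 1.2
#' @export
harmonicPathLength <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  n <- numVertices(g)
  if (numEdges(g) == 0L || n < 2L)
    return(Inf)
  d <- igraph::distances(asIgraph(g))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0  # disconnected pairs and the diagonal
  n * (n - 1) / sum(inv)
}

#' Degree-preserving surrogate network
#'
#' Randomizes a graph by repeated double-edge swaps
#' (a,b) + (c,d) -> (a,d) + (c,b), rejecting swaps that would create
#' self-loops or duplicate edges, so the surrogate keeps the vertex count,
#' edge count and the exact degree of every vertex.  10 x |E| swap
#' attempts are made.  If no valid swap exists (e.g. a star graph) the
#' input is returned unchanged.
#'
#' @param g a [BinaryGraph-class] with at least 2 edges.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A [BinaryGraph-class] with the same degree sequence as `g`.
#' @export
rewireSurrogate <- function(g, seed) {
  stopifnot(is(g, "BinaryGraph"))
  if (numEdges(g) < 2L)
    stop("rewiring requires at least 2 edges")
  ig <- asIgraph(g)
  rw <- withr::with_seed(as.integer(seed),
    igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                              niter = 10L * numEdges(g))))
  binaryGraph(numVertices(g), igraph::as_edgelist(rw, names = FALSE))
}

#' Surrogate-corrected small-world metrics
#'
#' Computes C and L of a graph together with their means C-s and L-s over
#' `nSurrogates` degree-preserving rewired surrogates, and the corrected
#' ratios gamma = C/C-s and lambda = L/L-s.  L-s averages the surrogates
#' with finite L; the number of edgeless (infinite-L) surrogates is
#' reported.  gamma is NA when C-s = 0; lambda is NA when no surrogate has
#' finite L.
#'
#' @param g a [BinaryGraph-class].
#' @param nSurrogates number of surrogates (default 50).
#' @param seed integer seed for the surrogate ensemble.
#' @return A list with `C`, `L`, `C_s`, `L_s`, `nInfiniteSurrogates`,
#'   `gamma`, `lambda`.
#' @export
correctedMetrics <- function(g, nSurrogates = 50L, seed = 1L) {
  stopifnot(nSurrogates >= 1L)
  C <- clusteringCoefficient(g)$global
  L <- harmonicPathLength(g)
  cs <- numeric(nSurrogates)
  ls <- numeric(nSurrogates)
  for (s in seq_len(nSurrogates)) {
    sg <- rewireSurrogate(g, seed = as.integer(seed) + s)
    cs[s] <- clusteringCoefficient(sg)$global
    ls[s] <- harmonicPathLength(sg)
  }
  finite <- is.finite(ls)
  C_s <- mean(cs)
  L_s <- if (any(finite)) mean(ls[finite]) else NA_real_
  list(C = C, L = L, C_s = C_s, L_s = L_s,
       nInfiniteSurrogates = sum(!finite),
       gamma = if (C_s > 0) C / C_s else NA_real_,
       lambda = if (is.na(L_s)) NA_real_ else L / L_s)
}

#' Theoretical small-world reference values
#'
#' Reference C and L for an ordered ring-like lattice (C = 3/4, L = N/2K)
#' and for a random graph (C = K/N, L = ln(N)/ln(K)) of N vertices and
#' mean degree K.
#'
#' @param n number of vertices N.
#' @param k mean degree K, with N > K > 1.
#' @return Named numeric vector `C_ordered`, `L_ordered`, `C_random`,
#'   `L_random`.
#' @examples
#' theoreticalReferences(116, 10)
#' @export
theoreticalReferences <- function(n, k) {
  if (k <= 1)
    stop("K must exceed 1 (log base degenerates at K <= 1)")
  stopifnot(n > k)
  c(C_ordered = 3 / 4, L_ordered = n / (2 * k),
    C_random = k / n, L_random = log(n) / log(k))
}

#' Metrics sweep over threshold or degree levels for a cohort
#'
#' For every subject and every level of the grid, binarizes the subject's
#' synchronization matrix (fixed threshold T or fixed mean degree K) and
#' computes the surrogate-corrected small-world metrics.
#'
#' @param matrices named list of [SyncMatrix-class], one per subject.
#' @param groups character vector of group labels aligned with `matrices`.
#' @param mode `"K"` (fixed mean degree) or `"T"` (fixed threshold).
#' @param levels numeric vector of K or T values; defaults 5:15 for K and
#'   seq(0.01, 0.05, by = 0.01) for T.
#' @param nSurrogates surrogates per subject and level (default 50).
#' @param seed integer master seed; per-(subject, level) surrogate streams
#'   are derived deterministically from it.
#' @return A long-format `data.frame` with columns subject_id, group,
#'   mode, level, C, L, C_s, L_s, n_inf_surrogates, gamma, lambda.
#' @export
cohortMetrics <- function(matrices, groups, mode = c("K", "T"),
                          levels = NULL, nSurrogates = 50L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(matrices) == length(groups))
  if (is.null(levels))
    levels <- if (mode == "K") 5:15 else seq(0.01, 0.05, by = 0.01)
  ids <- names(matrices)
  if (is.null(ids))
    ids <- paste0("sub", seq_along(matrices))
  rows <- vector("list", length(matrices) * length(levels))
  n <- 0L
  for (si in seq_along(matrices)) {
    for (li in seq_along(levels)) {
      g <- if (mode == "K")
        suppressWarnings(graphFromDegree(matrices[[si]], levels[li]))
      else
        graphFromThreshold(matrices[[si]], levels[li])
      cm <- correctedMetrics(g, nSurrogates = nSurrogates,
                             seed = as.integer(seed) + 1009L * si + 131L * li)
      n <- n + 1L
      rows[[n]] <- data.frame(subject_id = ids[si], group = groups[si],
                              mode = mode, level = levels[li],
                              C = cm$C, L = cm$L, C_s = cm$C_s,
                              L_s = cm$L_s,
                              n_inf_surrogates = cm$nInfiniteSurrogates,
                              gamma = cm$gamma, lambda = cm$lambda,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reshape a metrics table into per-group level matrices
#'
#' Helper for the group-level statistics: extracts one metric column from
#' a [cohortMetrics()] table as a subjects x levels matrix per group.
#'
#' @param metrics data.frame from [cohortMetrics()].
#' @param metric column name, e.g. `"lambda"`, `"L"`, `"C"`, `"gamma"`.
#' @return Named list of numeric matrices (rows = subjects, columns =
#'   levels, in increasing level order), one per group.
#' @export
metricByLevel <- function(metrics, metric = "lambda") {
  stopifnot(metric %in% names(metrics))
  levels <- sort(unique(metrics$level))
  out <- lapply(split(metrics, metrics$group), function(d) {
    ids <- unique(d$subject_id)
    m <- matrix(NA_real_, length(ids), length(levels),
                dimnames = list(ids, levels))
    m[cbind(match(d$subject_id, ids), match(d$level, levels))] <- d[[metric]]
    m
  })
  attr(out, "levels") <- levels
  out
}
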