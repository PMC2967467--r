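# Reference graph generators: the ordered ring lattice and the uniform
# random graph that anchor the small-world comparison.

#' Ring lattice
#'
#' A regular ring of `n` vertices where each vertex connects to its `k/2`
#' nearest neighbors on each side — the ordered end of the small-world
#' spectrum (C -> 3/4, L ~ N/2K for large rings).
#'
#' @param n number of vertices.
#' @param k even vertex degree, k < n.
#' @return A [BinaryGraph-class] that is k-regular.
#' @examples
#' degreeSequence(ringLattice(10, 4))
#' @export
ringLattice <- function(n, k) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k %% 2L != 0L)
    stop("'k' must be even")
  if (k >= n)
    stop("'k' must be smaller than 'n'")
  i <- rep(seq_len(n), each = k %/% 2L)
  step <- rep(seq_len(k %/% 2L), times = n)
  j <- (i - 1L + step) %% n + 1L
  binaryGraph(n, cbind(i, j))
}

#' Uniform random graph with a fixed edge count
#'
#' Draws a simple undirected graph uniformly among all graphs with `n`
#' vertices and exactly `nEdges` edges (the G(n, m) model) — the random
#' end of the small-world spectrum (C ~ K/N, L ~ ln(N)/ln(K)).
#'
#' @param n number of vertices.
#' @param nEdges number of edges, at most n(n-1)/2.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A [BinaryGraph-class] with exactly `nEdges` edges.
#' @export
randomGraph <- function(n, nEdges, seed) {
  n <- as.integer(n)
  if (nEdges > n * (n - 1) / 2)
    stop("'nEdges' exceeds the maximum ", n * (n - 1) / 2,
         " for n = ", n)
  ig <- withr::with_seed(as.integer(seed),
                         igraph::sample_gnm(n, nEdges, directed = FALSE))
  binaryGraph(n, igraph::as_edgelist(ig, names = FALSE))
}
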