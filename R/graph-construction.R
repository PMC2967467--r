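# Binarization of synchronization matrices: fixed threshold T or fixed
# mean degree K.

#' Threshold a synchronization matrix into a binary graph
#'
#' An edge joins regions i and j iff their synchronization strictly
#' exceeds the threshold T.
#'
#' @param x a [SyncMatrix-class].
#' @param threshold T, a number in (0, 1).
#' @return A [BinaryGraph-class] on the matrix's regions.
#' @seealso [graphFromDegree()]
#' @export
graphFromThreshold <- function(x, threshold) {
  stopifnot(is(x, "SyncMatrix"), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  v <- syncValues(x)
  idx <- which(upper.tri(v) & v > threshold, arr.ind = TRUE)
  binaryGraph(nrow(v), idx)
}

#' Fixed-mean-degree binarization
#'
#' Keeps the round(N * K / 2) strongest off-diagonal synchronization
#' values as edges, so that graphs built from different subjects at the
#' same K share an identical edge count regardless of their mean
#' synchronization level.  Ties are broken deterministically: descending
#' value, then ascending (i, j) lexicographic order.
#'
#' A warning is issued when the sparse-connectivity condition
#' N > K > ln(N) > 1 does not hold (K <= ln(N) no longer guarantees that a
#' comparable random graph is connected).
#'
#' @param x a [SyncMatrix-class].
#' @param k target mean degree, 0 < K < N.
#' @return A [BinaryGraph-class] with exactly round(N * K / 2) edges.
#' @seealso [graphFromThreshold()]
#' @export
graphFromDegree <- function(x, k) {
  stopifnot(is(x, "SyncMatrix"), length(k) == 1L, k > 0)
  v <- syncValues(x)
  n <- nrow(v)
  if (k >= n)
    stop("mean degree K = ", k, " must be smaller than N = ", n)
  if (!(k > log(n) && log(n) > 1))
    warning("K = ", k, " does not satisfy N > K > ln(N) > 1 (ln(N) = ",
            signif(log(n), 4), ")")
  nEdges <- round(n * k / 2)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  val <- v[ut]
  ord <- order(-val, ut[, 1L], ut[, 2L])
  binaryGraph(n, ut[ord[seq_len(nEdges)], , drop = FALSE])
}
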