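# Synchronization likelihood: time-delay embedding, rank-based critical
# distances, and coincident-recurrence counting between series pairs.

#' Time-delay embedding of a scalar series
#'
#' Reconstructs state vectors from a scalar series: vector i is
#' (x[i], x[i + lag], ..., x[i + (dim - 1) * lag]), giving
#' M = Tn - (dim - 1) * lag vectors.
#'
#' @param series numeric vector of length Tn.
#' @param params an [SlParams-class] object.
#' @return An M x dim numeric matrix of embedded state vectors.
#' @examples
#' embedSeries(c(1, 2, 3, 4), slParams(lag = 1, dim = 2, theiler = 0))
#' @export
embedSeries <- function(series, params = slParams()) {
  stopifnot(is(params, "SlParams"), is.numeric(series))
  l <- params@lag
  m <- params@dim
  w <- params@theiler
  minLen <- (m - 1L) * l + 2L * (w + 1L) + 1L
  if (length(series) < minLen)
    stop("series too short for embedding: length ", length(series),
         " but at least ", minLen, " samples are required for lag ", l,
         ", dimension ", m, " and Theiler window ", w)
  M <- length(series) - (m - 1L) * l
  idx <- seq_len(M)
  vapply(0:(m - 1L), function(k) series[idx + k * l], numeric(M))
}

#' Rank-based critical recurrence distance
#'
#' For embedded vector i, candidate vectors are those with
#' |i - j| > theiler.  The critical distance is the Euclidean distance of
#' the r-th nearest candidate, r = ceiling(pref * nCandidates), so that
#' the fraction of candidates within the returned distance is as close to
#' `pref` from above as the rank statistic allows.  Ties at the critical
#' distance all count as recurrences downstream.
#'
#' @param embedded M x m matrix from [embedSeries()].
#' @param i vector index (1-based).
#' @param params an [SlParams-class] object.
#' @return The critical distance, a nonnegative number.
#' @export
criticalDistance <- function(embedded, i, params = slParams()) {
  M <- nrow(embedded)
  stopifnot(i >= 1L, i <= M)
  cand <- which(abs(seq_len(M) - i) > params@theiler)
  if (!length(cand))
    stop("no recurrence candidates: Theiler window too wide for ", M,
         " embedded vectors")
  d <- sqrt(colSums((t(embedded[cand, , drop = FALSE]) -
                       embedded[i, ])^2))
  if (all(d == 0))
    stop("degenerate series: all candidate distances are zero")
  r <- max(1L, ceiling(params@pref * length(cand)))
  sort(d, partial = r)[r]
}

# Recurrence structure of one series: logical M x M matrix where entry
# (i, j) marks j as a recurrence of i (candidate within the critical
# distance), plus per-row recurrence counts.  This is the single place
# where the distance metric (Euclidean) and the <= epsilon tie rule live.
.recurrenceStructure <- function(series, params) {
  if (stats::var(series) == 0)
    stop("degenerate series: zero variance")
  E <- embedSeries(series, params)
  M <- nrow(E)
  D <- as.matrix(stats::dist(E))
  excluded <- abs(row(D) - col(D)) <= params@theiler
  D[excluded] <- Inf
  nCand <- M - rowSums(excluded)
  r <- pmax(1L, ceiling(params@pref * nCand))
  eps <- vapply(seq_len(M), function(i) {
    di <- D[i, is.finite(D[i, ])]
    if (all(di == 0))
      stop("degenerate series: all candidate distances are zero at i = ", i)
    sort(di, partial = r[i])[r[i]]
  }, numeric(1))
  rec <- D <= eps  # column-major recycling compares D[i, j] to eps[i]
  list(rec = rec, counts = rowSums(rec))
}

#' Synchronization likelihood between two series
#'
#' The SL between series x and y is the average probability that a pattern
#' recurrence in x coincides in time with a pattern recurrence in y.  Both
#' series are delay-embedded; for each reference time i the recurrences of
#' x (candidates within x's critical distance) are intersected with those
#' of y and normalized by the number of x-recurrences.  The two
#' conditional directions (x given y, y given x) are averaged, yielding a
#' symmetric measure in [0, 1]: about `pref` for independent series and
#' exactly 1 for identical series.
#'
#' SL depends on each series only through distance ranks among its own
#' embedded vectors, so it is invariant to affine rescaling a * x + b
#' (a > 0) of either input.
#'
#' @param x,y numeric vectors of equal length.
#' @param params an [SlParams-class] object.
#' @return A single number in [0, 1].
#' @examples
#' s <- sin(seq(0, 8 * pi, length.out = 120)) + rnorm(120, sd = 0.1)
#' slPair(s, s)  # exactly 1
#' @export
slPair <- function(x, y, params = slParams()) {
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y))
  rx <- .recurrenceStructure(x, params)
  ry <- .recurrenceStructure(y, params)
  joint <- rowSums(rx$rec & ry$rec)
  sl <- 0.5 * (mean(joint / rx$counts) + mean(joint / ry$counts))
  min(max(sl, 0), 1)
}

#' Pairwise synchronization matrix of a subject
#'
#' Computes [slPair()] for all R(R-1)/2 region pairs of one subject.  The
#' per-region recurrence structures are computed once and reused across
#' pairs, which gives results identical to independent slPair calls.
#'
#' @param subject a [RegionalTimeSeries-class] object.
#' @param params an [SlParams-class] object.
#' @return A [SyncMatrix-class] with the subject's region labels.
#' @export
slMatrix <- function(subject, params = slParams()) {
  stopifnot(is(subject, "RegionalTimeSeries"))
  v <- subject@values
  R <- nrow(v)
  rv <- apply(v, 1L, stats::var)
  if (any(rv == 0))
    stop("degenerate region series: ",
         paste(rownames(v)[rv == 0], collapse = ", "))
  rec <- lapply(seq_len(R), function(r)
    .recurrenceStructure(v[r, ], params))
  out <- diag(1, R)
  for (i in seq_len(R - 1L)) {
    ri <- rec[[i]]
    for (j in seq.int(i + 1L, R)) {
      rj <- rec[[j]]
      joint <- rowSums(ri$rec & rj$rec)
      sl <- 0.5 * (mean(joint / ri$counts) + mean(joint / rj$counts))
      out[i, j] <- out[j, i] <- min(max(sl, 0), 1)
    }
  }
  syncMatrix(out, labels = rownames(v))
}
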