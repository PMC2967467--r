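# Group comparisons: per-level two-sample t statistics, the cluster-based
# permutation test over adjacent threshold levels, and the pairwise
# regional synchronization difference map.

# Pooled-variance two-sample t per column of X (n x L), group1 - group2.
# Zero pooled variance at a level yields t = 0 there.
.tPerLevel <- function(X, g1) {
  n1 <- sum(g1)
  n2 <- sum(!g1)
  x1 <- X[g1, , drop = FALSE]
  x2 <- X[!g1, , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  ss1 <- colSums(x1^2) - n1 * m1^2
  ss2 <- colSums(x2^2) - n2 * m2^2
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

#' Per-level two-sample t statistics
#'
#' Pooled-variance (Student) two-sample t statistics comparing group 1
#' against group 2 separately at each threshold level, oriented as
#' group1 - group2, with df = n1 + n2 - 2.  Welch's unequal-variance t is
#' available as an option.  A level with zero pooled variance yields
#' t = 0 with a warning.
#'
#' @param group1,group2 numeric matrices, subjects x levels, with the same
#'   level grid (columns).
#' @param levels optional numeric vector labelling the columns.
#' @param welch if TRUE use Welch's t (df then varies by level).
#' @return A list with `levels`, `t`, `df`.
#' @examples
#' levelTstats(matrix(c(1, 2, 3)), matrix(c(4, 5, 6)))$t  # -3.674
#' @export
levelTstats <- function(group1, group2, levels = NULL, welch = FALSE) {
  group1 <- as.matrix(group1)
  group2 <- as.matrix(group2)
  stopifnot(ncol(group1) == ncol(group2),
            nrow(group1) >= 2L, nrow(group2) >= 2L)
  if (is.null(levels))
    levels <- seq_len(ncol(group1))
  n1 <- nrow(group1)
  n2 <- nrow(group2)
  if (welch) {
    v1 <- apply(group1, 2L, stats::var) / n1
    v2 <- apply(group2, 2L, stats::var) / n2
    se <- sqrt(v1 + v2)
    t <- (colMeans(group1) - colMeans(group2)) / se
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    if (any(se == 0)) {
      warning("zero variance at ", sum(se == 0), " level(s); t set to 0")
      t[se == 0] <- 0
      df[se == 0] <- n1 + n2 - 2
    }
  } else {
    X <- rbind(group1, group2)
    t <- .tPerLevel(X, rep(c(TRUE, FALSE), c(n1, n2)))
    if (any(t == 0 & .zeroPooledVar(group1, group2)))
      warning("zero pooled variance at one or more levels; t set to 0")
    df <- n1 + n2 - 2
  }
  list(levels = levels, t = unname(t), df = df)
}

.zeroPooledVar <- function(g1, g2) {
  apply(g1, 2L, stats::var) + apply(g2, 2L, stats::var) == 0
}

# Maximal runs of adjacent supra-threshold t values of a common sign;
# returns the cluster table and the max |cluster sum| statistic.
.clusterStat <- function(t, thr) {
  sgn <- integer(length(t))
  sgn[t > thr] <- 1L
  sgn[t < -thr] <- -1L
  if (!any(sgn != 0L))
    return(list(clusters = data.frame(start = integer(), end = integer(),
                                      sum = numeric(), sign = integer()),
                stat = 0))
  r <- rle(sgn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  sums <- mapply(function(s, e) sum(t[s:e]), starts[keep], ends[keep])
  list(clusters = data.frame(start = starts[keep], end = ends[keep],
                             sum = sums, sign = r$values[keep]),
       stat = max(abs(sums)))
}

#' Cluster-based permutation test over threshold levels
#'
#' Controls the family-wise error of comparing two groups across many
#' adjacent threshold levels.  Per-level pooled t statistics are cut at
#' the 2.5th/97.5th quantiles of the t distribution with n1 + n2 - 2 df;
#' supra-threshold values at adjacent levels of a common sign are joined
#' into clusters and summed; the test statistic is the maximum absolute
#' cluster sum.  Its null distribution is built by repartitioning the
#' subjects into two groups of the original sizes — exhaustively when the
#' number of distinct repartitions is at most `maxExhaustive`, otherwise
#' by `nPermutations` Monte-Carlo draws with the add-one convention
#' p = (#{perm >= observed} + 1) / (B + 1).  With no observed
#' supra-threshold cluster, p = 1.
#'
#' @param group1,group2 numeric matrices, subjects x levels (same grid).
#' @param levels optional numeric labels for the level grid.
#' @param nPermutations Monte-Carlo permutations (default 5000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param clusterAlpha two-sided tail probability defining the
#'   supra-threshold cut (default 0.05, i.e. the 2.5th/97.5th quantiles).
#' @param exact `"auto"` (exhaustive when feasible), `"always"`, or
#'   `"never"`.
#' @param maxExhaustive largest repartition count enumerated exhaustively.
#' @return An object of class `slClusterTest`: list with `levels`, `t`,
#'   `df`, `threshold`, `clusters` (data.frame start/end/sum/sign),
#'   `maxStat`, `pValue`, `nPermutations`, `exhaustive`.
#' @export
clusterPermutationTest <- function(group1, group2, levels = NULL,
                                   nPermutations = 5000L, seed = 1L,
                                   clusterAlpha = 0.05,
                                   exact = c("auto", "always", "never"),
                                   maxExhaustive = 20000L) {
  exact <- match.arg(exact)
  group1 <- as.matrix(group1)
  group2 <- as.matrix(group2)
  n1 <- nrow(group1)
  n2 <- nrow(group2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 subjects")
  stopifnot(ncol(group1) == ncol(group2))
  if (nPermutations < 100L)
    warning("fewer than 100 permutations gives a coarse p-value")
  if (is.null(levels))
    levels <- seq_len(ncol(group1))
  df <- n1 + n2 - 2
  thr <- stats::qt(1 - clusterAlpha / 2, df)
  X <- rbind(group1, group2)
  n <- n1 + n2
  memb <- rep(c(TRUE, FALSE), c(n1, n2))
  tObs <- .tPerLevel(X, memb)
  obs <- .clusterStat(tObs, thr)

  nTotal <- choose(n, n1)
  doExhaustive <- exact == "always" ||
    (exact == "auto" && nTotal <= maxExhaustive)
  permStat <- function(g1idx) {
    g <- logical(n)
    g[g1idx] <- TRUE
    .clusterStat(.tPerLevel(X, g), thr)$stat
  }
  eps <- 1e-12
  if (doExhaustive) {
    combs <- utils::combn(n, n1)
    stats <- apply(combs, 2L, permStat)
    p <- mean(stats >= obs$stat - eps)
    B <- ncol(combs)
  } else {
    stats <- withr::with_seed(as.integer(seed),
      vapply(seq_len(nPermutations),
             function(b) permStat(sample.int(n, n1)), numeric(1)))
    p <- (sum(stats >= obs$stat - eps) + 1) / (nPermutations + 1)
    B <- as.integer(nPermutations)
  }
  if (nrow(obs$clusters) == 0L)
    p <- 1
  structure(list(levels = levels, t = tObs, df = df, threshold = thr,
                 clusters = obs$clusters, maxStat = obs$stat, pValue = p,
                 nPermutations = B, exhaustive = doExhaustive),
            class = "slClusterTest")
}

#' @export
print.slClusterTest <- function(x, ...) {
  cat("Cluster-based permutation test\n")
  cat(sprintf("  levels: %s\n", paste(signif(x$levels, 4), collapse = " ")))
  cat(sprintf("  t threshold (df = %d): +/-%.3f\n", x$df, x$threshold))
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold cluster\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: levels %s..%s, summed t = %.3f\n", i,
                  signif(x$levels[x$clusters$start[i]], 4),
                  signif(x$levels[x$clusters$end[i]], 4),
                  x$clusters$sum[i]))
  }
  cat(sprintf("  max |cluster sum| = %.3f, p = %.4g (%s, %d repartitions)\n",
              x$maxStat, x$pValue,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$nPermutations))
  invisible(x)
}

#' Regional synchronization difference map
#'
#' Pairwise two-sample t-tests (pooled variance, two-tailed, uncorrected)
#' comparing the synchronization of every region pair between two groups
#' of subjects.  The sign map is +1 where group 1's mean synchronization
#' is larger and p < alpha, -1 where smaller and p < alpha, 0 elsewhere.
#' No multiple-testing correction is applied by design; the map is meant
#' to be read at the level of regional patterns, not single pairs.
#'
#' @param group1,group2 lists of [SyncMatrix-class] with identical region
#'   labels (e.g. patients as `group1` so +1 means increased in patients).
#' @param alpha uncorrected significance level (default 0.05).
#' @return An object of class `slRegionalMap`: list with `signs` (R x R
#'   matrix in -1/0/+1), `pValues`, `tValues`, `alpha`, `labels`.
#' @export
regionalDifferenceMap <- function(group1, group2, alpha = 0.05) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  labels <- regionLabels(group1[[1L]])
  all <- c(group1, group2)
  if (!all(vapply(all, function(m)
    identical(regionLabels(m), labels), logical(1))))
    stop("all synchronization matrices must share the same region labels")
  n1 <- length(group1)
  n2 <- length(group2)
  M1 <- vapply(group1, syncValues, matrix(0, length(labels), length(labels)))
  M2 <- vapply(group2, syncValues, matrix(0, length(labels), length(labels)))
  dim(M1) <- c(length(labels)^2, n1)
  dim(M2) <- c(length(labels)^2, n2)
  m1 <- rowMeans(M1)
  m2 <- rowMeans(M2)
  ss1 <- rowSums(M1^2) - n1 * m1^2
  ss2 <- rowSums(M2^2) - n2 * m2^2
  df <- n1 + n2 - 2
  se <- sqrt((ss1 + ss2) / df * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0] <- 1
  R <- length(labels)
  tm <- matrix(t, R, R, dimnames = list(labels, labels))
  pm <- matrix(p, R, R, dimnames = list(labels, labels))
  signs <- matrix(0L, R, R, dimnames = list(labels, labels))
  signs[pm < alpha & tm > 0] <- 1L
  signs[pm < alpha & tm < 0] <- -1L
  diag(signs) <- 0L
  diag(pm) <- 1
  diag(tm) <- 0
  structure(list(signs = signs, pValues = pm, tValues = tm,
                 alpha = alpha, labels = labels),
            class = "slRegionalMap")
}

#' @export
print.slRegionalMap <- function(x, ...) {
  up <- upper.tri(x$signs)
  cat(sprintf(paste0("Regional synchronization difference map: ",
                     "%d regions, alpha = %g (uncorrected)\n"),
              length(x$labels), x$alpha))
  cat(sprintf("  +1 pairs: %d, -1 pairs: %d of %d\n",
              sum(x$signs[up] == 1L), sum(x$signs[up] == -1L), sum(up)))
  invisible(x)
}

#' Aggregate a difference map by lobe-block pairs
#'
#' Counts the significantly increased (+1) and decreased (-1) region
#' pairs of a [regionalDifferenceMap()] within each unordered pair of
#' lobe blocks, the reporting granularity at which regional synchrony
#' patterns are interpreted.
#'
#' @param map an `slRegionalMap`.
#' @param registry ROI registry data.frame covering all map regions
#'   (columns `region`, `block`).
#' @return A data.frame with columns block1, block2, nPos, nNeg, nPairs.
#' @export
blockSummary <- function(map, registry) {
  stopifnot(inherits(map, "slRegionalMap"))
  idx <- match(map$labels, registry$region)
  if (anyNA(idx))
    stop("regions missing from registry: ",
         paste(map$labels[is.na(idx)], collapse = ", "))
  blk <- as.character(registry$block)[idx]
  ut <- which(upper.tri(map$signs), arr.ind = TRUE)
  b1 <- pmin(blk[ut[, 1L]], blk[ut[, 2L]])
  b2 <- pmax(blk[ut[, 1L]], blk[ut[, 2L]])
  s <- map$signs[ut]
  key <- paste(b1, b2, sep = "|")
  agg <- lapply(split(seq_along(key), key), function(ii)
    data.frame(block1 = b1[ii[1L]], block2 = b2[ii[1L]],
               nPos = sum(s[ii] == 1L), nNeg = sum(s[ii] == -1L),
               nPairs = length(ii), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$block1, out$block2), ]
}
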