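#' @import methods
NULL

#' Embedding and recurrence parameters for synchronization likelihood
#'
#' Holds the time-delay embedding lag, embedding dimension, Theiler window
#' and reference recurrence probability used throughout the SL computation.
#'
#' @slot lag integer, embedding lag in samples (>= 1).
#' @slot dim integer, embedding dimension (>= 2).
#' @slot theiler integer, Theiler window in samples (>= 0); candidate
#'   recurrences with |i - j| <= theiler are excluded to suppress
#'   autocorrelation artifacts.
#' @slot pref numeric in (0, 1), the reference probability fixing the
#'   per-timepoint fraction of nearest recurrences that count as a pattern
#'   match.  Under independence the expected SL is approximately pref.
#'
#' @seealso [slParams()], [slPair()], [slMatrix()]
#' @exportClass SlParams
setClass("SlParams",
         representation(lag = "integer", dim = "integer",
                        theiler = "integer", pref = "numeric"))

setValidity("SlParams", function(object) {
  msg <- character()
  if (length(object@lag) != 1L || object@lag < 1L)
    msg <- c(msg, "'lag' must be a single integer >= 1")
  if (length(object@dim) != 1L || object@dim < 2L)
    msg <- c(msg, "'dim' must be a single integer >= 2")
  if (length(object@theiler) != 1L || object@theiler < 0L)
    msg <- c(msg, "'theiler' must be a single integer >= 0")
  if (length(object@pref) != 1L || !is.finite(object@pref) ||
      object@pref <= 0 || object@pref >= 1)
    msg <- c(msg, "'pref' must be a single number in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct SL parameters
#'
#' Defaults are a lag of 1 sample, embedding dimension 6, Theiler window 6
#' and a reference probability of 0.01 — the standard settings for
#' resting-state BOLD series of ~200 volumes.
#'
#' @param lag embedding lag in samples.
#' @param dim embedding dimension.
#' @param theiler Theiler window in samples.
#' @param pref reference recurrence probability in (0, 1).
#' @return An [SlParams-class] object.
#' @examples
#' slParams()
#' slParams(lag = 2L, dim = 4L)
#' @export
slParams <- function(lag = 1L, dim = 6L, theiler = 6L, pref = 0.01) {
  new("SlParams", lag = as.integer(lag), dim = as.integer(dim),
      theiler = as.integer(theiler), pref = as.numeric(pref))
}

#' One subject's regional time-series
#'
#' A regions-by-timepoints real matrix of ROI-averaged BOLD signals for a
#' single subject, with the repetition time and the subject's group label.
#'
#' @slot subjectId character scalar.
#' @slot group character scalar, "control" or "patient".
#' @slot values numeric matrix, regions in rows (rownames are the region
#'   labels), timepoints in columns.  All entries finite; every row must
#'   have nonzero variance.
#' @slot trSeconds positive numeric, sampling interval (TR) in seconds.
#'
#' @seealso [regionalTimeSeries()], [simulateCohort()], [slMatrix()]
#' @exportClass RegionalTimeSeries
setClass("RegionalTimeSeries",
         representation(subjectId = "character", group = "character",
                        values = "matrix", trSeconds = "numeric"))

setValidity("RegionalTimeSeries", function(object) {
  msg <- character()
  v <- object@values
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "'subjectId' must be a nonempty string")
  if (length(object@group) != 1L ||
      !object@group %in% c("control", "patient"))
    msg <- c(msg, "'group' must be \"control\" or \"patient\"")
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  else {
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "'values' must have unique region rownames")
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "'values' must be finite with no NaN")
    else {
      rv <- apply(v, 1L, stats::var)
      if (any(rv == 0))
        msg <- c(msg, paste0("constant region series: ",
                             paste(rownames(v)[rv == 0], collapse = ", ")))
    }
  }
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0)
    msg <- c(msg, "'trSeconds' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionalTimeSeries
#'
#' @param subjectId subject identifier.
#' @param group "control" or "patient".
#' @param values regions x timepoints numeric matrix with region rownames.
#' @param trSeconds sampling interval in seconds (default 2.85).
#' @return A [RegionalTimeSeries-class] object.
#' @export
regionalTimeSeries <- function(subjectId, group, values, trSeconds = 2.85) {
  new("RegionalTimeSeries", subjectId = as.character(subjectId),
      group = as.character(group), values = values,
      trSeconds = as.numeric(trSeconds))
}

#' Pairwise synchronization matrix
#'
#' Symmetric R x R matrix of pairwise synchronization likelihood values
#' between regional time-series.  Off-diagonal entries lie in [0, 1]; the
#' diagonal is fixed at 1 by convention (self-synchronization) and is
#' excluded from all derived statistics and from graph construction.
#'
#' @slot values numeric symmetric matrix with identical row/column region
#'   dimnames, unit diagonal, off-diagonal entries in [0, 1].
#'
#' @seealso [syncMatrix()], [slMatrix()], [globalSyncMean()]
#' @exportClass SyncMatrix
setClass("SyncMatrix", representation(values = "matrix"))

setValidity("SyncMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || nrow(v) != ncol(v))
    return("'values' must be a square numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)) ||
      !identical(rownames(v), colnames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "row and column names must be identical unique labels")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "entries must be finite")
  else {
    if (max(abs(v - t(v))) > 1e-8)
      msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v) - 1) > 1e-12))
      msg <- c(msg, "diagonal must equal 1")
    off <- v[upper.tri(v)]
    if (any(off < 0 | off > 1))
      msg <- c(msg, "off-diagonal entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SyncMatrix
#'
#' @param values square symmetric numeric matrix; the diagonal is set to 1.
#' @param labels optional region labels (defaults to existing dimnames).
#' @return A [SyncMatrix-class] object.
#' @export
syncMatrix <- function(values, labels = rownames(values)) {
  if (is.null(labels))
    labels <- paste0("R", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  diag(values) <- 1
  new("SyncMatrix", values = values)
}

#' Undirected binary graph
#'
#' A simple undirected graph on n vertices, stored as a two-column integer
#' edge matrix with each edge recorded once as (i, j), i < j.  No
#' self-loops, no duplicate edges.
#'
#' @slot nVertices integer, number of vertices.
#' @slot edges integer matrix with two columns; possibly zero rows.
#'
#' @seealso [binaryGraph()], [graphFromThreshold()], [graphFromDegree()]
#' @exportClass BinaryGraph
setClass("BinaryGraph",
         representation(nVertices = "integer", edges = "matrix"))

setValidity("BinaryGraph", function(object) {
  n <- object@nVertices
  e <- object@edges
  msg <- character()
  if (length(n) != 1L || n < 1L)
    msg <- c(msg, "'nVertices' must be a single positive integer")
  if (!is.integer(e) || ncol(e) != 2L)
    return(c(msg, "'edges' must be an integer matrix with two columns"))
  if (nrow(e)) {
    if (any(e < 1L) || any(e > n))
      msg <- c(msg, "vertex indices out of range")
    if (any(e[, 1L] >= e[, 2L]))
      msg <- c(msg, "edges must satisfy i < j (no self-loops)")
    if (anyDuplicated(e))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryGraph
#'
#' Edge pairs are normalized to (min, max) order, sorted, and validated to
#' be a simple graph.
#'
#' @param nVertices number of vertices.
#' @param edges two-column matrix of vertex index pairs (may have 0 rows).
#' @return A [BinaryGraph-class] object.
#' @examples
#' g <- binaryGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' numEdges(g)
#' @export
binaryGraph <- function(nVertices, edges = matrix(integer(), 0L, 2L)) {
  edges <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  new("BinaryGraph", nVertices = as.integer(nVertices), edges = edges)
}

#' Synthetic cohort configuration
#'
#' Describes a two-group cohort of regional time-series generated from a
#' latent-factor model: one latent Gaussian signal per lobe block plus one
#' global signal, region loadings taken from a symmetric block-pair
#' coupling matrix, additive Gaussian noise, and a moving-average smoothing
#' that emulates slow BOLD temporal autocorrelation.  Patients use
#' `baseCoupling + adEffect` as their loading matrix.
#'
#' @slot nControl,nPatient integer group sizes.
#' @slot nTimepoints integer number of volumes per subject.
#' @slot blockMap named character vector mapping each region to its lobe
#'   block; its names define the regions and their order.
#' @slot baseCoupling symmetric numeric matrix of per-block-pair latent
#'   loadings in [0, 1], with block names on both dimensions.
#' @slot adEffect symmetric numeric matrix of additive per-block-pair
#'   deltas; `baseCoupling + adEffect` must stay within [0, 1].
#' @slot noiseSd positive numeric, innovation noise SD.
#' @slot globalLoading numeric in [0, 1], loading of the shared global
#'   signal present in every region.
#' @slot smoothWindow odd positive integer, moving-average width (samples).
#' @slot trSeconds positive numeric, TR in seconds.
#' @slot seed integer master seed; per-subject streams are derived as
#'   `seed + 101 * subjectIndex`.
#'
#' @seealso [cohortConfig()], [simulateCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
         representation(nControl = "integer", nPatient = "integer",
                        nTimepoints = "integer", blockMap = "character",
                        baseCoupling = "matrix", adEffect = "matrix",
                        noiseSd = "numeric", globalLoading = "numeric",
                        smoothWindow = "integer", trSeconds = "numeric",
                        seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nControl < 1L || object@nPatient < 1L)
    msg <- c(msg, "group sizes must be >= 1")
  if (object@nTimepoints < 8L)
    msg <- c(msg, "'nTimepoints' must be >= 8")
  bm <- object@blockMap
  if (is.null(names(bm)) || anyDuplicated(names(bm)))
    msg <- c(msg, "'blockMap' must have unique region names")
  bc <- object@baseCoupling
  ae <- object@adEffect
  blocks <- rownames(bc)
  if (is.null(blocks) || !identical(blocks, colnames(bc)))
    msg <- c(msg, "'baseCoupling' must have matching block dimnames")
  else {
    if (!all(bm %in% blocks))
      msg <- c(msg, "blockMap refers to blocks missing from baseCoupling")
    if (max(abs(bc - t(bc))) > 1e-12)
      msg <- c(msg, "'baseCoupling' must be symmetric")
    if (any(bc < 0 | bc > 1))
      msg <- c(msg, "'baseCoupling' entries must lie in [0, 1]")
    if (!identical(dimnames(ae), dimnames(bc)))
      msg <- c(msg, "'adEffect' dimnames must match 'baseCoupling'")
    else {
      if (max(abs(ae - t(ae))) > 1e-12)
        msg <- c(msg, "'adEffect' must be symmetric")
      if (any(bc + ae < 0 | bc + ae > 1))
        msg <- c(msg, "'baseCoupling' + 'adEffect' must stay within [0, 1]")
    }
  }
  if (object@noiseSd <= 0)
    msg <- c(msg, "'noiseSd' must be positive")
  if (object@globalLoading < 0 || object@globalLoading > 1)
    msg <- c(msg, "'globalLoading' must lie in [0, 1]")
  if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L)
    msg <- c(msg, "'smoothWindow' must be a positive odd integer")
  if (object@trSeconds <= 0)
    msg <- c(msg, "'trSeconds' must be positive")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "SlParams", function(object) {
  cat("SlParams: lag =", object@lag, ", dim =", object@dim,
      ", theiler =", object@theiler, ", pref =", object@pref, "\n")
})

#' @export
setMethod("show", "RegionalTimeSeries", function(object) {
  cat("RegionalTimeSeries", object@subjectId,
      sprintf("(%s): %d regions x %d timepoints, TR = %gs\n",
              object@group, nrow(object@values), ncol(object@values),
              object@trSeconds))
})

#' @export
setMethod("show", "SyncMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("SyncMatrix: %d regions, mean off-diagonal SL = %.4f\n",
              nrow(v), mean(off)))
})

#' @export
setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph: %d vertices, %d edges (mean degree %.2f)\n",
              object@nVertices, nrow(object@edges),
              2 * nrow(object@edges) / object@nVertices))
})

#' @export
setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0("CohortConfig: %d controls + %d patients, ",
                     "%d regions x %d timepoints, seed %d\n"),
              object@nControl, object@nPatient, length(object@blockMap),
              object@nTimepoints, object@seed))
})
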