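#' Accessors for SLgraph classes
#'
#' Small accessor generics: region labels, underlying numeric values,
#' subject metadata, graph sizes and degree sequences.
#'
#' @param x an SLgraph object.
#' @return The corresponding slot content; see methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("syncValues", function(x) standardGeneric("syncValues"))

#' @rdname accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))

#' @rdname accessors
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname accessors
#' @export
setGeneric("degreeSequence", function(x) standardGeneric("degreeSequence"))

#' Whole-brain mean synchronization
#'
#' Mean of the strictly off-diagonal entries of a synchronization matrix
#' (the diagonal self-synchronization of 1 carries no information and is
#' excluded).
#'
#' @param x a [SyncMatrix-class] or a plain square symmetric matrix.
#' @return A single number, the global mean synchronization S.
#' @examples
#' m <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3, 3)
#' globalSyncMean(m)  # 0.4
#' @export
setGeneric("globalSyncMean", function(x) standardGeneric("globalSyncMean"))

#' Convert to an igraph object
#'
#' @param x a [BinaryGraph-class].
#' @return An undirected simple `igraph` graph with the same vertices and
#'   edges.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname accessors
setMethod("regionLabels", "RegionalTimeSeries",
          function(x) rownames(x@values))

#' @rdname accessors
setMethod("regionLabels", "SyncMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("syncValues", "SyncMatrix", function(x) x@values)

#' @rdname accessors
setMethod("tsValues", "RegionalTimeSeries", function(x) x@values)

#' @rdname accessors
setMethod("subjectId", "RegionalTimeSeries", function(x) x@subjectId)

#' @rdname accessors
setMethod("subjectGroup", "RegionalTimeSeries", function(x) x@group)

#' @rdname accessors
setMethod("numVertices", "BinaryGraph", function(x) x@nVertices)

#' @rdname accessors
setMethod("numEdges", "BinaryGraph", function(x) nrow(x@edges))

#' @rdname accessors
setMethod("edgeMatrix", "BinaryGraph", function(x) x@edges)

#' @rdname accessors
setMethod("degreeSequence", "BinaryGraph", function(x) {
  tabulate(as.vector(x@edges), nbins = x@nVertices)
})

#' @rdname globalSyncMean
setMethod("globalSyncMean", "SyncMatrix",
          function(x) mean(x@values[upper.tri(x@values)]))

#' @rdname globalSyncMean
setMethod("globalSyncMean", "matrix", function(x) {
  stopifnot(nrow(x) == ncol(x))
  mean(x[upper.tri(x)])
})

#' @rdname asIgraph
setMethod("asIgraph", "BinaryGraph", function(x) {
  igraph::make_graph(edges = as.vector(t(x@edges)), n = x@nVertices,
                     directed = FALSE)
})
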