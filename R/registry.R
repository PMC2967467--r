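# ROI registry: region names, hemisphere, lobe block, cerebellum flag.

.registryColumns <- c("region", "hemisphere", "block", "cerebellum")

#' Load a ROI registry
#'
#' Reads and validates a tab-separated registry with columns `region`,
#' `hemisphere` (L/R/midline), `block` (lobe grouping) and `cerebellum`
#' (logical flag).
#'
#' @param path TSV file path; defaults to the bundled 116-region atlas.
#' @return A validated data.frame.
#' @seealso [aalRegistry()], [excludeCerebellum()], [subsetRegistry()]
#' @export
loadRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aal_registry.tsv", package = "SLgraph",
                        mustWork = TRUE)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.registryColumns, names(reg))
  if (length(missing))
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(reg$region))
    stop("duplicate region names: ",
         paste(unique(reg$region[duplicated(reg$region)]), collapse = ", "))
  if (!all(reg$hemisphere %in% c("L", "R", "midline")))
    stop("hemisphere must be L, R or midline")
  reg$cerebellum <- as.logical(reg$cerebellum)
  if (anyNA(reg$cerebellum))
    stop("cerebellum flag must be logical")
  reg
}

#' The bundled 116-region anatomical registry
#'
#' The automated anatomical labelling parcellation: 116 regions (54 per
#' hemisphere plus 8 midline vermis structures), of which 26 are
#' cerebellar, each assigned to one of six lobe blocks (frontal,
#' temporal-L, temporal-R, parieto-occipital, subcortical, cerebellar).
#' The block assignment is a documented approximation used for block-level
#' summaries and for the synthetic cohort generator.
#'
#' @return A data.frame with 116 rows.
#' @examples
#' table(aalRegistry()$hemisphere)
#' @export
aalRegistry <- function() loadRegistry()

#' Remove cerebellar regions from a registry and cohort
#'
#' Drops the rows flagged `cerebellum` from the registry and the matching
#' rows from every subject's time-series matrix, preserving the order of
#' the retained regions.  With the bundled registry this reduces 116
#' regions to 90.
#'
#' @param registry a registry data.frame.
#' @param subjects optional list of [RegionalTimeSeries-class] whose row
#'   labels must all be covered by the registry.
#' @return If `subjects` is NULL, the filtered registry; otherwise a list
#'   with elements `registry` and `subjects`.
#' @export
excludeCerebellum <- function(registry, subjects = NULL) {
  keepNames <- registry$region[!registry$cerebellum]
  out <- registry[!registry$cerebellum, , drop = FALSE]
  rownames(out) <- NULL
  if (is.null(subjects))
    return(out)
  subjects <- lapply(subjects, function(s) {
    labs <- regionLabels(s)
    if (!all(labs %in% registry$region))
      stop("subject ", subjectId(s), " has regions not in the registry: ",
           paste(setdiff(labs, registry$region), collapse = ", "))
    keep <- labs %in% keepNames
    regionalTimeSeries(subjectId(s), subjectGroup(s),
                       tsValues(s)[keep, , drop = FALSE],
                       trSeconds = s@trSeconds)
  })
  list(registry = out, subjects = subjects)
}

#' Subset a registry to a few regions per block
#'
#' Takes the first `n` registry rows of each requested lobe block, in
#' registry order — a convenience for scaled-down simulations that keep
#' the full block structure.
#'
#' @param registry a registry data.frame.
#' @param nPerBlock named integer vector, e.g.
#'   `c(frontal = 8, "parieto-occipital" = 6)`; blocks not named are
#'   dropped entirely.
#' @return The reduced registry (row order of the original preserved).
#' @export
subsetRegistry <- function(registry, nPerBlock) {
  stopifnot(!is.null(names(nPerBlock)))
  unknown <- setdiff(names(nPerBlock), unique(registry$block))
  if (length(unknown))
    stop("unknown block(s): ", paste(unknown, collapse = ", "))
  keep <- unlist(lapply(names(nPerBlock), function(b) {
    rows <- which(registry$block == b)
    utils::head(rows, nPerBlock[[b]])
  }))
  out <- registry[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
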