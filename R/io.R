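# Plain-text I/O: subject matrices, synchronization matrices, cohort
# manifests and key-value run manifests, all tab-separated.

#' Write / read a subject's regional time-series matrix
#'
#' Regions in rows (labels as row names), timepoints in columns.
#'
#' @param x a [RegionalTimeSeries-class].
#' @param path TSV file path.
#' @return `writeSubjectMatrix` returns `path` invisibly;
#'   `readSubjectMatrix` returns a [RegionalTimeSeries-class].
#' @name subjectIO
#' @export
writeSubjectMatrix <- function(x, path) {
  stopifnot(is(x, "RegionalTimeSeries"))
  m <- tsValues(x)
  colnames(m) <- paste0("t", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname subjectIO
#' @param subjectId,group,trSeconds metadata for the subject being read.
#' @export
readSubjectMatrix <- function(path, subjectId, group, trSeconds = 2.85) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  colnames(m) <- NULL
  regionalTimeSeries(subjectId, group, m, trSeconds = trSeconds)
}

#' Write / read a synchronization matrix
#'
#' Square TSV with region labels as both row and column headers.
#'
#' @param x a [SyncMatrix-class].
#' @param path TSV file path.
#' @return `writeSyncMatrix` returns `path` invisibly; `readSyncMatrix`
#'   returns a [SyncMatrix-class].
#' @name syncIO
#' @export
writeSyncMatrix <- function(x, path) {
  stopifnot(is(x, "SyncMatrix"))
  utils::write.table(syncValues(x), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname syncIO
#' @export
readSyncMatrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  syncMatrix(m)
}

#' Write a cohort to a directory
#'
#' One TSV per subject plus a `manifest.tsv` with columns subject_id,
#' group, tr_seconds, file.
#'
#' @param subjects list of [RegionalTimeSeries-class].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
writeCohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(subjects, function(s) {
    f <- paste0(subjectId(s), ".tsv")
    writeSubjectMatrix(s, file.path(dir, f))
    data.frame(subject_id = subjectId(s), group = subjectGroup(s),
               tr_seconds = s@trSeconds, file = f,
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `manifest.tsv` and subject TSVs.
#' @return Named list of [RegionalTimeSeries-class].
#' @export
readCohort <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(manifest)), function(i)
    readSubjectMatrix(file.path(dir, manifest$file[i]),
                      manifest$subject_id[i], manifest$group[i],
                      manifest$tr_seconds[i]))
  stats::setNames(out, manifest$subject_id)
}

# Flat key-value manifest (one "key<TAB>value" line per entry).
.writeKeyValue <- function(x, path) {
  lines <- vapply(names(x), function(k)
    paste(k, paste(format(x[[k]], trim = TRUE), collapse = ","),
          sep = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
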