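#' Validate a sample annotation table
#'
#' The annotation is a plain data.frame with one row per sample. Required
#' columns: `sample_id` (unique) and `disease_class` (one of `normal`,
#' `primary`, `metastatic`). Optional survival columns come in pairs —
#' `os_time`/`os_event` (overall survival, months) and
#' `rfs_time`/`rfs_event` (recurrence-free survival) — where an event flag
#' may only be present when the paired time is present, times are
#' non-negative, and events are 0/1. Any further columns are treated as
#' clinical covariates (age group, Gleason score, stage, ...).
#'
#' @param ann data.frame to validate.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_annotation <- function(ann) {
  if (!is.data.frame(ann)) stop("annotation must be a data.frame")
  for (col in c("sample_id", "disease_class"))
    if (!col %in% names(ann)) stop("annotation lacks required column '", col, "'")
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(ann$disease_class), c("normal", "primary", "metastatic"))
  if (length(bad) || anyNA(ann$disease_class))
    stop("disease_class must be one of normal/primary/metastatic; found: ",
         paste(bad, collapse = ", "))
  for (ep in c("os", "rfs")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (ecol %in% names(ann) && !tcol %in% names(ann))
      stop("'", ecol, "' present without '", tcol, "'")
    if (all(c(tcol, ecol) %in% names(ann))) {
      orphan <- !is.na(ann[[ecol]]) & is.na(ann[[tcol]])
      if (any(orphan))
        stop("event flag without time for sample(s): ",
             paste(ann$sample_id[orphan], collapse = ", "))
      if (any(ann[[tcol]] < 0, na.rm = TRUE))
        stop("'", tcol, "' must be non-negative")
      if (!all(ann[[ecol]] %in% c(0, 1, NA)))
        stop("'", ecol, "' must be 0/1")
    }
  }
  invisible(ann)
}

#' Read a sample annotation TSV
#'
#' Expected columns: `sample_id`, optionally `cohort`, `disease_class`,
#' survival columns `os_time, os_event, rfs_time, rfs_event`, plus free
#' covariate columns; literal `NA` for absent values.
#'
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  validate_annotation(ann)
  ann
}

#' Write a sample annotation TSV
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align annotation rows to the matrix's samples, erroring on mismatch.
align_annotation <- function(m, ann) {
  validate_annotation(ann)
  missing <- setdiff(sample_ids(m), ann$sample_id)
  if (length(missing))
    stop("samples missing from annotation: ", paste(missing, collapse = ", "))
  ann[match(sample_ids(m), ann$sample_id), , drop = FALSE]
}

# rbind a list of single-row data.frames; NULL for an empty list.
rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
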