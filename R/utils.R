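`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Check a counts matrix
#'
#' Validates a gene-by-sample count matrix: numeric, non-negative,
#' integer-valued, with unique row (gene) and column (sample) names.
#'
#' @param counts matrix of counts, genes in rows, samples in columns.
#' @return the matrix, invisibly, after validation.
#' @keywords internal
check_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix (genes x samples)")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) stopf("counts must be integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("counts must have unique rownames (gene ids)")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stopf("counts must have unique colnames (sample ids)")
  invisible(counts)
}

#' Check sample metadata against a count matrix
#'
#' @param sample_info data.frame with columns `sample_id`, `group`,
#'   `subject_id`, `timepoint` (and optionally `covid_history`).
#' @param counts optional count matrix whose columns must all be
#'   described in `sample_info`.
#' @return `sample_info` with factors normalised, invisibly.
#' @keywords internal
check_sample_info <- function(sample_info, counts = NULL) {
  need <- c("sample_id", "group", "subject_id", "timepoint")
  miss <- setdiff(need, names(sample_info))
  if (length(miss))
    stopf("sample_info is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sample_info$sample_id))
    stopf("duplicate sample_id in sample_info")
  ## each subject belongs to exactly one group
  tab <- unique(sample_info[, c("subject_id", "group")])
  if (anyDuplicated(tab$subject_id))
    stopf("a subject_id maps to more than one group")
  if (!is.null(counts)) {
    absent <- setdiff(colnames(counts), sample_info$sample_id)
    if (length(absent))
      stopf("samples in counts but not in sample_info: %s",
            paste(head(absent, 5), collapse = ", "))
  }
  invisible(sample_info)
}

## deterministic sub-seed derivation: keeps every derived seed a valid
## 32-bit integer whatever the root seed
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
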