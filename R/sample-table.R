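#' Validate a sample metadata table
#'
#' The cohort design table: one row per RNA sample, with the grouping
#' variables used throughout the analysis. `arm` is the biologic class the
#' patient started (TNFi or IL17Ai), `timepoint` is baseline or month3,
#' `response` encodes low disease activity at 3 months.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `arm`,
#'   `timepoint`, `response`, `batch` (and optionally `dapsa`).
#' @return the validated data.frame, classed `SampleTable`.
#' @export
sample_table <- function(df) {
  req <- c("sample_id", "patient_id", "arm", "timepoint", "response", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in req) df[[col]] <- as.character(df[[col]])
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample_id(s): ", paste(dup, collapse = ", "))
  chk <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad)) {
      stop(sprintf("invalid %s value(s): %s (allowed: %s)",
                   col, paste(bad, collapse = ", "),
                   paste(allowed, collapse = ", ")))
    }
  }
  chk("arm", c("TNFi", "IL17Ai"))
  chk("timepoint", c("baseline", "month3"))
  chk("response", c("responder", "nonresponder"))
  if (anyDuplicated(df[, c("patient_id", "timepoint")])) {
    stop("a patient may have at most one sample per timepoint")
  }
  if ("dapsa" %in% names(df)) {
    df$dapsa <- as.numeric(df$dapsa)
    if (any(df$dapsa < 0, na.rm = TRUE)) stop("dapsa must be non-negative")
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path TSV with the columns documented in [sample_table()].
#' @return a `SampleTable`.
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.delim(path, stringsAsFactors = FALSE,
                                 colClasses = "character"))
}

#' @rdname read_sample_table
#' @param meta a `SampleTable`.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that every sample of an expression matrix is described
#'
#' @param m an `ExpressionMatrix`.
#' @param meta a `SampleTable`.
#' @return invisibly `TRUE`; errors if a sample is unresolved.
#' @export
check_samples_resolve <- function(m, meta) {
  miss <- setdiff(colnames(m), meta$sample_id)
  if (length(miss)) {
    stop("expression sample(s) missing from metadata: ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
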