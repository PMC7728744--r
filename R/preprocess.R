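#' Convert FPKM to TPM
#'
#' Within-sample renormalisation: each column is scaled so its values sum
#' to one million. Proportional columns therefore become identical, and
#' re-applying the operation is a no-op.
#'
#' @param m an `ExpressionMatrix` on the `fpkm` scale.
#' @return an `ExpressionMatrix` on the `tpm` scale.
#' @export
fpkm_to_tpm <- function(m) {
  if (em_scale(m) != "fpkm") stop("input must be on the fpkm scale")
  v <- as.matrix(unclass(m))
  totals <- colSums(v)
  zero <- colnames(v)[totals == 0]
  if (length(zero)) {
    stop("all-zero sample column(s): ", paste(zero, collapse = ", "))
  }
  expression_matrix(sweep(v, 2, totals, "/") * 1e6, "tpm")
}

#' Log-transform a TPM matrix
#'
#' Elementwise `log2(x + 1)`: monotone, zero maps to zero.
#'
#' @param m an `ExpressionMatrix` on the `tpm` scale.
#' @return an `ExpressionMatrix` on the `log2_tpm1` scale.
#' @export
log_transform <- function(m) {
  if (em_scale(m) != "tpm") stop("input must be on the tpm scale")
  v <- as.matrix(unclass(m))
  if (any(v < 0)) stop("negative values cannot be log-transformed")
  expression_matrix(log2(v + 1), "log2_tpm1")
}

#' Adjust batch effects by per-gene location-scale standardization
#'
#' For every gene, each batch's values are shifted and scaled to the gene's
#' pooled mean and pooled standard deviation across all samples. Genes with
#' zero variance within a batch are shifted only (no rescaling), so the
#' operation never divides by zero. A single-batch matrix passes through
#' unchanged, and each gene's pooled mean is preserved exactly.
#'
#' This is a deliberately simple adjustment operating on the log scale; it
#' removes additive/multiplicative batch offsets but performs no
#' empirical-Bayes shrinkage across genes.
#'
#' @param m an `ExpressionMatrix` on the `log2_tpm1` scale.
#' @param meta a `SampleTable` with a `batch` label for every sample; each
#'   batch needs at least 2 samples.
#' @return the adjusted `ExpressionMatrix`.
#' @export
adjust_batches <- function(m, meta) {
  if (em_scale(m) != "log2_tpm1") stop("batch adjustment operates on the log scale")
  check_samples_resolve(m, meta)
  v <- as.matrix(unclass(m))
  batch <- meta$batch[match(colnames(v), meta$sample_id)]
  counts <- table(batch)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    stop("batch(es) with a single sample: ", paste(small, collapse = ", "),
         "; merge them with another batch or skip adjustment")
  }
  if (length(counts) == 1L) return(m)
  pooled_mean <- rowMeans(v)
  pooled_sd <- apply(v, 1, stats::sd)
  out <- v
  for (b in names(counts)) {
    idx <- which(batch == b)
    bm <- rowMeans(v[, idx, drop = FALSE])
    bs <- apply(v[, idx, drop = FALSE], 1, stats::sd)
    ratio <- ifelse(bs > 0 & pooled_sd > 0, pooled_sd / bs, 1)
    out[, idx] <- (v[, idx, drop = FALSE] - bm) * ratio + pooled_mean
  }
  expression_matrix(out, "log2_tpm1")
}

#' Median-center each gene row
#'
#' The display convention used for clustering heatmaps: after centering,
#' every row's median is exactly zero.
#'
#' @param m an `ExpressionMatrix`.
#' @return an `ExpressionMatrix` on the same scale tag as the input is not
#'   meaningful after centering, so the result keeps `log2_tpm1`.
#' @export
median_center_rows <- function(m) {
  v <- as.matrix(unclass(m))
  med <- apply(v, 1, stats::median)
  expression_matrix(v - med, "log2_tpm1")
}
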