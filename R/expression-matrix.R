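#' Construct an expression matrix with an explicit measurement scale
#'
#' The central data container of the pipeline: a genes-by-samples numeric
#' matrix tagged with the scale its values live on. Downstream operations
#' check the tag so that, e.g., a TPM normalisation is never applied to
#' already-log-transformed data.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param scale one of `"fpkm"`, `"tpm"`, `"log2_tpm1"`.
#' @return a numeric matrix of class `ExpressionMatrix` with a `scale`
#'   attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("A", "B", "C"), c("s1", "s2"))), "tpm")
#' em_scale(m)
#' @export
expression_matrix <- function(values, scale = c("fpkm", "tpm", "log2_tpm1")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(values) == 0L) {
    stop("expression matrix is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g)) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s)) {
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("expression matrix contains non-finite values")
  }
  if (scale %in% c("fpkm", "tpm") && any(values < 0)) {
    stop("negative values are not allowed on the ", scale, " scale")
  }
  structure(values, scale = scale, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param m an `ExpressionMatrix`.
#' @export
em_scale <- function(m) {
  sc <- attr(m, "scale")
  if (is.null(sc)) stop("object carries no scale tag; not an ExpressionMatrix?")
  sc
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
    nrow(x), ncol(x), em_scale(x)
  ))
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds gene symbols.
#' Duplicate gene rows are collapsed by keeping the row with the larger
#' total signal (with a warning); a duplicated sample id in the header is an
#' error.
#'
#' @param path TSV file path.
#' @param scale measurement scale of the stored values (see
#'   [expression_matrix()]).
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(path, scale = c("fpkm", "tpm", "log2_tpm1")) {
  scale <- match.arg(scale)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    stop("malformed header in ", path, ": need a gene column plus >= 1 sample")
  }
  samples <- header[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup)) {
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(dup, collapse = ", "))
  }
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty expression matrix in ", path)
  genes <- raw[[1]]
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(raw[[j + 1L]]) & raw[[j + 1L]] != "NA")
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' at gene '%s', sample '%s' in %s",
        raw[[j + 1L]][bad[1]], genes[bad[1]], samples[j], path
      ))
    }
    vals[, j] <- col
  }
  if (anyDuplicated(genes)) {
    totals <- rowSums(vals)
    keep <- rep(TRUE, length(genes))
    for (g in unique(genes[duplicated(genes)])) {
      idx <- which(genes == g)
      best <- idx[which.max(totals[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
    warning(sprintf(
      "%d duplicate gene row(s) collapsed in %s (kept max-total-signal row)",
      sum(!keep), path
    ))
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  expression_matrix(vals, scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: first column `gene`, one column per
#' sample.
#'
#' @param m an `ExpressionMatrix`.
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.matrix(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
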