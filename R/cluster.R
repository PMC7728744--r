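#' Correlation dissimilarity between samples
#'
#' `d(i, j) = 1 - Pearson(column i, column j)` over the selected genes;
#' identical columns are at distance 0, perfectly anti-correlated columns
#' at 2.
#'
#' @param m an `ExpressionMatrix` (samples in columns).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
pearson_distance_matrix <- function(m) {
  v <- as.matrix(unclass(m))
  if (nrow(v) < 2L) stop("need at least 2 genes")
  sds <- apply(v, 2, stats::sd)
  bad <- colnames(v)[sds == 0]
  if (length(bad)) {
    stop("zero-variance sample column(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Wraps `stats::hclust(method = "average")` on a precomputed
#' dissimilarity; merge heights are the mean pairwise dissimilarity
#' between the joined clusters, and ties resolve to the smallest pair of
#' cluster indices.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal (or a
#'   `dist`).
#' @return an `hclust` object.
#' @export
average_linkage <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (anyNA(d)) stop("dissimilarity matrix contains NA")
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12) ||
        any(diag(d) != 0)) {
      stop("d must be square and symmetric with a zero diagonal")
    }
    d <- stats::as.dist(d)
  }
  if (anyNA(d)) stop("dissimilarity matrix contains NA")
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param dend an `hclust` object.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector of cluster labels per sample.
#' @export
cut_k <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  stats::cutree(dend, k = k)
}

#' PCA of samples on a gene subset
#'
#' Genes are centered (no unit-variance scaling); components carry a
#' deterministic sign convention (the largest-|loading| gene of each
#' component is made positive).
#'
#' @param m an `ExpressionMatrix`.
#' @param genes genes to project on (>= 2, all present in `m`).
#' @return a `PCAResult` list: `scores` (samples x components),
#'   `loadings` (genes x components), `var_explained` (fractions summing
#'   to 1 over all components).
#' @export
pca_samples <- function(m, genes = rownames(m)) {
  v <- as.matrix(unclass(m))
  miss <- setdiff(genes, rownames(v))
  if (length(miss)) {
    stop("gene(s) not in matrix: ", paste(utils::head(miss, 10), collapse = ", "))
  }
  if (length(genes) < 2L) stop("need at least 2 genes")
  if (ncol(v) < 2L) stop("need at least 2 samples")
  x <- t(v[genes, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve),
            class = "PCAResult")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a predicted clustering and the true
#' labels: 1 for identical partitions, about 0 for independent ones,
#' negative for worse-than-chance agreement.
#'
#' @param labels_predicted,labels_true label vectors over the same
#'   samples.
#' @return ARI in `[-1, 1]`.
#' @export
separation_score <- function(labels_predicted, labels_true) {
  if (length(labels_predicted) != length(labels_true)) {
    stop("label vectors must have equal length")
  }
  tab <- table(labels_predicted, labels_true)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' End-to-end responder-separation analysis for one comparison
#'
#' The clustering/PCA view: take the top-k best-p DEGs of a comparison,
#' optionally median-center rows, cluster the comparison's samples with
#' correlation distance + UPGMA, cut at k = 2, and score the agreement
#' with the true group labels by ARI; also returns the PCA of the same
#' samples on the same genes.
#'
#' @param m an `ExpressionMatrix` on the analysis scale.
#' @param cmp a resolved `ComparisonSpec`.
#' @param tbl the comparison's `DGETable`.
#' @param cfg a `RunConfig` (`fc_seed`, `p_seed`, `top_k`).
#' @param median_center center rows before the distance computation
#'   (display convention; on by default).
#' @return list: `genes`, `dendrogram`, `clusters`, `ari`, `pca`,
#'   `true_labels`.
#' @export
cluster_comparison <- function(m, cmp, tbl, cfg = run_config(),
                               median_center = TRUE) {
  genes <- suppressWarnings(
    top_k_by_p(tbl, deg_criteria(cfg$fc_seed, cfg$p_seed), cfg$top_k)
  )
  if (length(genes) < 2L) stop("fewer than 2 qualifying DEGs")
  samples <- c(cmp$g1_samples, cmp$g2_samples)
  sub <- expression_matrix(
    as.matrix(unclass(m))[genes, samples, drop = FALSE], "log2_tpm1"
  )
  dm <- if (median_center) median_center_rows(sub) else sub
  dend <- average_linkage(pearson_distance_matrix(dm))
  clusters <- cut_k(dend, 2)
  truth <- setNames(
    rep(c("group1", "group2"), c(length(cmp$g1_samples), length(cmp$g2_samples))),
    samples
  )
  list(
    genes = genes,
    dendrogram = dend,
    clusters = clusters,
    ari = separation_score(clusters[samples], truth[samples]),
    pca = pca_samples(sub),
    true_labels = truth
  )
}
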