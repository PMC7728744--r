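#' Pathway-membership DEG rule
#'
#' The union gate used for pathway annotation: a gene counts as a DEG when
#' its |fold change| is at or above `fc_member_hi` regardless of p, or
#' when it falls in the half-open band `[fc_member_lo, fc_member_hi)` and
#' its raw p-value is at most `p_member`. The band is half-open so a gene
#' is never counted by both clauses.
#'
#' @param fc_signed signed linear fold change(s).
#' @param p raw p-value(s).
#' @param cfg a `RunConfig` supplying `fc_member_hi`, `fc_member_lo`,
#'   `p_member`.
#' @return logical vector.
#' @export
member_deg_rule <- function(fc_signed, p, cfg = run_config()) {
  afc <- abs(fc_signed)
  afc >= cfg$fc_member_hi |
    (afc >= cfg$fc_member_lo & afc < cfg$fc_member_hi & p <= cfg$p_member)
}

#' DEG membership of a pathway family across comparisons
#'
#' Annotates the union gene set of a pathway family (e.g. the
#' keyword-retrieved Rho-GTPase pathways) with the [member_deg_rule()]
#' outcome in every comparison, and aggregates to pathway-level DEG
#' counts. Family genes absent from a comparison's DGE table are reported
#' as unmeasured, never silently dropped.
#'
#' @param family a `GeneSetDB` (typically from
#'   [retrieve_sets_by_keyword()]).
#' @param dge_tables named list of `DGETable`s, one per comparison.
#' @param cfg a `RunConfig`.
#' @return a `MembershipMatrix` list: `counts` (pathway x comparison DEG
#'   counts), `gene_incidence` (union gene x comparison logical),
#'   `union_size`, `n_single_comparison` (genes DEG in exactly one
#'   comparison), `pathways_with_deg`, `unmeasured` (genes missing from
#'   at least one DGE table).
#' @export
build_membership <- function(family, dge_tables, cfg = run_config()) {
  stopifnot(inherits(family, "GeneSetDB"), length(family$sets) >= 1,
            length(dge_tables) >= 1)
  if (is.null(names(dge_tables)) || any(names(dge_tables) == "")) {
    stop("dge_tables must be a named list (one name per comparison)")
  }
  genes <- sort(unique(unlist(family$sets, use.names = FALSE)))
  comps <- names(dge_tables)
  inc <- matrix(FALSE, length(genes), length(comps),
                dimnames = list(genes, comps))
  unmeasured <- character()
  for (cc in comps) {
    tbl <- dge_tables[[cc]]
    idx <- match(genes, tbl$gene)
    unmeasured <- union(unmeasured, genes[is.na(idx)])
    ok <- !is.na(idx)
    inc[ok, cc] <- member_deg_rule(tbl$fc_signed[idx[ok]], tbl$p[idx[ok]], cfg)
  }
  counts <- matrix(0, length(family$sets), length(comps),
                   dimnames = list(names(family$sets), comps))
  for (nm in names(family$sets)) {
    counts[nm, ] <- colSums(inc[rownames(inc) %in% family$sets[[nm]], ,
                                drop = FALSE])
  }
  structure(list(
    counts = counts,
    gene_incidence = inc,
    union_size = length(genes),
    n_single_comparison = sum(rowSums(inc) == 1L),
    pathways_with_deg = rownames(counts)[rowSums(counts) > 0],
    unmeasured = sort(unmeasured)
  ), class = "MembershipMatrix")
}

#' @export
print.MembershipMatrix <- function(x, ...) {
  cat(sprintf(
    "MembershipMatrix: %d pathway(s) x %d comparison(s); %d union gene(s), %d DEG in exactly one comparison\n",
    nrow(x$counts), ncol(x$counts), x$union_size, x$n_single_comparison
  ))
  invisible(x)
}

#' Pairwise comparison overlap of family DEGs
#'
#' Entry (i, j) counts union genes that are DEGs in both comparison i and
#' comparison j; the diagonal holds per-comparison DEG counts.
#'
#' @param mm a `MembershipMatrix` with >= 2 comparisons.
#' @return symmetric integer matrix, comparisons x comparisons.
#' @export
comparison_overlap_matrix <- function(mm) {
  stopifnot(inherits(mm, "MembershipMatrix"))
  if (ncol(mm$gene_incidence) < 2L) stop("need at least 2 comparisons")
  crossprod(mm$gene_incidence * 1L)
}

#' Per-gene fold-change / p-value profile of one pathway
#'
#' The per-pathway table view: one row per pathway gene, with fold change
#' and p-value columns for every comparison. By default rows are
#' restricted to genes passing [member_deg_rule()] in at least one
#' comparison; set `include_all` to keep every measured member.
#'
#' @param pathway character vector of member genes.
#' @param dge_tables named list of `DGETable`s.
#' @param cfg a `RunConfig`.
#' @param include_all keep members that never pass the DEG rule.
#' @return data.frame: `gene`, `measured`, then `fc_<comparison>` and
#'   `p_<comparison>` column pairs; rows ordered by gene symbol.
#' @export
profile_pathway <- function(pathway, dge_tables, cfg = run_config(),
                            include_all = FALSE) {
  stopifnot(length(pathway) >= 1, length(dge_tables) >= 1)
  genes <- sort(unique(as.character(pathway)))
  comps <- names(dge_tables)
  out <- data.frame(gene = genes, measured = TRUE, stringsAsFactors = FALSE)
  pass_any <- rep(FALSE, length(genes))
  for (cc in comps) {
    tbl <- dge_tables[[cc]]
    idx <- match(genes, tbl$gene)
    out$measured <- out$measured & !is.na(idx)
    fc <- tbl$fc_signed[idx]
    p <- tbl$p[idx]
    ok <- !is.na(idx)
    pass_any[ok] <- pass_any[ok] | member_deg_rule(fc[ok], p[ok], cfg)
    out[[paste0("fc_", cc)]] <- fc
    out[[paste0("p_", cc)]] <- p
  }
  if (!include_all) out <- out[pass_any, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two paired profiles
#'
#' Utility for correlating e.g. mRNA and protein abundance of a gene
#' across tissues. Pairs with a missing value in either vector are
#' dropped; at least 3 complete pairs and non-zero variance on both sides
#' are required.
#'
#' @param x,y paired numeric vectors.
#' @return list with `r` (Pearson coefficient), `p` (two-sided, t-based)
#'   and `n` (complete pairs used).
#' @export
correlate_profiles <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the profiles")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Write membership/profile outputs as TSV
#'
#' @param mm a `MembershipMatrix`.
#' @param prefix output path prefix; writes `<prefix>_counts.tsv`,
#'   `<prefix>_incidence.tsv` and `<prefix>_overlap.tsv`.
#' @export
write_membership <- function(mm, prefix) {
  wt <- function(m, path) {
    df <- data.frame(rownames(m), m * 1, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- "id"
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(mm$counts, paste0(prefix, "_counts.tsv"))
  wt(mm$gene_incidence, paste0(prefix, "_incidence.tsv"))
  if (ncol(mm$gene_incidence) >= 2L) {
    wt(comparison_overlap_matrix(mm), paste0(prefix, "_overlap.tsv"))
  }
  invisible(prefix)
}
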