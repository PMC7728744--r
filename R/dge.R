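#' Signed linear fold change from a log2 difference
#'
#' Maps a log2 mean difference to the signed linear convention used for
#' all fold-change gates: `2^d` for `d >= 0`, `-2^(-d)` otherwise, so the
#' magnitude is always >= 1 and -1.5 reads "1.5-fold lower in group 1".
#'
#' @param log2fc numeric vector of log2 differences.
#' @return signed linear fold changes.
#' @export
signed_fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc))
}

#' Per-gene fold change for a comparison
#'
#' Fold change is the mean log2 expression of group 1 minus group 2,
#' reported both as `log2fc` and as the signed linear `fc_signed`.
#'
#' @param m an `ExpressionMatrix` on the `log2_tpm1` scale.
#' @param cmp a resolved `ComparisonSpec`.
#' @return data.frame with columns `gene`, `log2fc`, `fc_signed`.
#' @export
compute_fold_change <- function(m, cmp) {
  gs <- .comparison_groups(m, cmp)
  log2fc <- rowMeans(gs$v1) - rowMeans(gs$v2)
  data.frame(gene = rownames(m), log2fc = log2fc,
             fc_signed = signed_fc(log2fc),
             row.names = NULL, stringsAsFactors = FALSE)
}

.comparison_groups <- function(m, cmp) {
  stopifnot(inherits(cmp, "ComparisonSpec"))
  if (is.null(cmp$g1_samples) || is.null(cmp$g2_samples)) {
    stop("comparison '", cmp$name,
         "' is unresolved; call resolve_comparison() first")
  }
  v <- as.matrix(unclass(m))
  miss <- setdiff(c(cmp$g1_samples, cmp$g2_samples), colnames(v))
  if (length(miss)) {
    stop("comparison '", cmp$name, "': sample(s) not in matrix: ",
         paste(miss, collapse = ", "))
  }
  list(v1 = v[, cmp$g1_samples, drop = FALSE],
       v2 = v[, cmp$g2_samples, drop = FALSE])
}

#' Estimate empirical-Bayes variance-moderation parameters
#'
#' Fits a scaled inverse-chi-square prior to the observed per-gene sample
#' variances by moment matching on the log scale. Writing `z = log(s2)`
#' and correcting for the chi-square sampling layer at `df_resid` degrees
#' of freedom, the excess dispersion of `z` beyond `trigamma(df/2)`
#' identifies the prior degrees of freedom `d0` (via the inverse trigamma),
#' and the corrected mean identifies the prior variance `s0_sq`. When the
#' observed dispersion is at or below the sampling minimum the prior is
#' degenerate: `d0 = Inf` and `s0_sq = mean(s2)`.
#'
#' @param s2 per-gene sample variances (>= 10 must be positive).
#' @param df_resid residual degrees of freedom each variance was computed
#'   with.
#' @return a `ModerationParams` list with elements `d0` and `s0_sq`.
#' @export
estimate_moderation <- function(s2, df_resid) {
  s2 <- as.numeric(s2)
  if (all(s2 == 0)) stop("all variances are zero; cannot estimate a prior")
  pos <- s2[s2 > 0]
  if (length(pos) < 10L) {
    stop("need at least 10 genes with positive variance (have ",
         length(pos), ")")
  }
  df <- as.numeric(df_resid)
  stopifnot(length(df) == 1L, df > 0)
  e <- log(pos) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    params <- list(d0 = Inf, s0_sq = mean(pos))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    params <- list(d0 = d0,
                   s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(params, class = "ModerationParams")
}

# Newton iteration for trigamma^{-1}(y), monotone decreasing on (0, Inf)
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Construct moderation parameters explicitly
#'
#' Mostly useful for reductions and tests: `d0 = 0` disables moderation
#' (the classical test), `d0 = Inf` forces every gene to the prior
#' variance.
#'
#' @param d0 prior degrees of freedom (>= 0, `Inf` allowed).
#' @param s0_sq prior variance (> 0).
#' @return a `ModerationParams` list.
#' @export
moderation_params <- function(d0, s0_sq) {
  stopifnot(d0 >= 0, s0_sq > 0)
  structure(list(d0 = d0, s0_sq = s0_sq), class = "ModerationParams")
}

#' Moderated t-test for one comparison
#'
#' Per-gene two-group test with empirical-Bayes variance shrinkage. The
#' posterior variance is
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, the statistic
#' `t = log2fc / sqrt(s2_post * (1/n1 + 1/n2))` (or `s2_post / n` for
#' paired data), and the two-sided p-value comes from a t-distribution with
#' `d0 + df` degrees of freedom. With `d0 = 0` this reduces exactly to the
#' classical pooled-variance two-sample t-test (or paired t-test).
#'
#' @param m an `ExpressionMatrix` on the `log2_tpm1` scale.
#' @param cmp a resolved `ComparisonSpec` with >= 2 samples per group
#'   (>= 2 pairs when paired).
#' @param params a `ModerationParams`; if `NULL`, estimated from this
#'   comparison's variances.
#' @param paired override the comparison's pairing flag.
#' @return a `DGETable` data.frame: `gene`, `log2fc`, `fc_signed`, `s2`,
#'   `s2_post`, `t`, `df` (total, `d0 + df_resid`), `p`.
#' @export
moderated_t <- function(m, cmp, params = NULL, paired = cmp$paired) {
  gs <- .comparison_groups(m, cmp)
  v1 <- gs$v1
  v2 <- gs$v2
  if (paired) {
    if (ncol(v1) != ncol(v2)) stop("paired groups differ in size")
    n <- ncol(v1)
    if (n < 2L) stop("paired test needs >= 2 pairs")
    d <- v1 - v2
    log2fc <- rowMeans(d)
    s2 <- apply(d, 1, stats::var)
    df_resid <- n - 1
    se_factor <- 1 / n
  } else {
    n1 <- ncol(v1)
    n2 <- ncol(v2)
    if (n1 < 2L || n2 < 2L) stop("unpaired test needs >= 2 samples per group")
    log2fc <- rowMeans(v1) - rowMeans(v2)
    var1 <- apply(v1, 1, stats::var)
    var2 <- apply(v2, 1, stats::var)
    df_resid <- n1 + n2 - 2
    s2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / df_resid
    se_factor <- 1 / n1 + 1 / n2
  }
  if (is.null(params)) params <- estimate_moderation(s2, df_resid)
  stopifnot(inherits(params, "ModerationParams"))
  d0 <- params$d0
  s0 <- params$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else {
    (d0 * s0 + df_resid * s2) / (d0 + df_resid)
  }
  se <- sqrt(s2_post * se_factor)
  t <- ifelse(se > 0, log2fc / se,
              ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(abs(t), df = df_total, lower.tail = FALSE)
  structure(
    data.frame(gene = rownames(m), log2fc = log2fc,
               fc_signed = signed_fc(log2fc),
               s2 = s2, s2_post = s2_post, t = t,
               df = df_total, p = p,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("DGETable", "data.frame"),
    comparison = cmp$name, d0 = d0, s0_sq = s0
  )
}

#' DEG selection criteria
#'
#' @param min_abs_fc linear fold-change gate (>= 1).
#' @param max_p raw p-value gate, used only when `require_p`.
#' @param require_p whether the p gate applies ("regardless of p value"
#'   gates set this to `FALSE`).
#' @return a `DEGCriteria` list.
#' @export
deg_criteria <- function(min_abs_fc, max_p = 0.05, require_p = TRUE) {
  stopifnot(min_abs_fc >= 1, max_p > 0, max_p <= 1)
  structure(list(min_abs_fc = min_abs_fc, max_p = max_p,
                 require_p = isTRUE(require_p)),
            class = "DEGCriteria")
}

#' Select differentially expressed genes
#'
#' Applies the fold-change (and optionally p-value) gates and returns the
#' qualifying genes ordered by ascending p, ties broken by descending
#' |fold change|, then by symbol, so the ranking is fully deterministic.
#'
#' @param tbl a `DGETable`.
#' @param crit a `DEGCriteria`.
#' @return character vector of gene symbols (possibly empty).
#' @export
select_degs <- function(tbl, crit) {
  stopifnot(inherits(crit, "DEGCriteria"))
  keep <- abs(tbl$fc_signed) >= crit$min_abs_fc
  if (crit$require_p) keep <- keep & tbl$p <= crit$max_p
  sub <- tbl[keep, , drop = FALSE]
  sub$gene[order(sub$p, -abs(sub$fc_signed), sub$gene)]
}

#' Top-k DEGs by p-value
#'
#' The first `k` genes of the [select_degs()] ordering; warns when fewer
#' than `k` genes qualify.
#'
#' @inheritParams select_degs
#' @param k number of genes requested (>= 1).
#' @return character vector of at most `k` gene symbols.
#' @export
top_k_by_p <- function(tbl, crit, k) {
  stopifnot(k >= 1)
  degs <- select_degs(tbl, crit)
  if (length(degs) < k) {
    warning(sprintf("only %d gene(s) qualify (requested %d)",
                    length(degs), k))
  }
  utils::head(degs, k)
}

#' Write a DGE table as TSV
#'
#' @param tbl a `DGETable`.
#' @param path output file.
#' @export
write_dge_table <- function(tbl, path) {
  cols <- c("gene", "log2fc", "fc_signed", "t", "df", "p")
  utils::write.table(as.data.frame(tbl)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
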