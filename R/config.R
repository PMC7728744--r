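#' Analysis thresholds and run parameters
#'
#' Every threshold driving the analysis in one declarative object. Defaults
#' are the conventional gates of the workflow: seed DEGs at linear fold
#' change >= 1.4 with raw p <= 0.05, network expansion at fold change >=
#' 1.2 regardless of p, pathway-membership union rule combining both, and
#' top-100 DEGs for the clustering/PCA views.
#'
#' @param fc_seed linear fold-change gate for seed DEGs.
#' @param p_seed raw p-value gate for seed DEGs.
#' @param fc_expand fold-change gate for PPI expansion (no p gate).
#' @param fc_member_hi fold change at or above which a pathway gene counts
#'   as DEG regardless of p.
#' @param fc_member_lo lower edge of the membership band `[lo, hi)` where a
#'   p-value gate applies.
#' @param p_member p gate inside the membership band.
#' @param top_k number of best-p DEGs used for clustering/PCA.
#' @param fdr_alpha BH-adjusted significance level for enrichment.
#' @param n_permutations replicates for the randomization overlap test.
#' @param rng_seed integer seed for all stochastic steps.
#' @param expansion_mode `"seed_anchored"` (qualifying edges must touch a
#'   seed) or `"pairwise"` (any qualifying pair).
#' @param use_batch_adjusted whether differential expression runs on the
#'   batch-adjusted matrix (when batches are present).
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(fc_seed = 1.4, p_seed = 0.05,
                       fc_expand = 1.2,
                       fc_member_hi = 1.4, fc_member_lo = 1.2,
                       p_member = 0.05,
                       top_k = 100, fdr_alpha = 0.05,
                       n_permutations = 1000, rng_seed = 1L,
                       expansion_mode = c("seed_anchored", "pairwise"),
                       use_batch_adjusted = TRUE) {
  expansion_mode <- match.arg(expansion_mode)
  cfg <- list(
    fc_seed = fc_seed, p_seed = p_seed, fc_expand = fc_expand,
    fc_member_hi = fc_member_hi, fc_member_lo = fc_member_lo,
    p_member = p_member, top_k = as.integer(top_k),
    fdr_alpha = fdr_alpha, n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed), expansion_mode = expansion_mode,
    use_batch_adjusted = isTRUE(use_batch_adjusted)
  )
  with(cfg, {
    stopifnot(
      fc_member_lo > 1, fc_member_lo <= fc_member_hi,
      fc_seed >= 1, fc_expand >= 1,
      p_seed > 0, p_seed < 1, p_member > 0, p_member < 1,
      fdr_alpha > 0, fdr_alpha < 1,
      top_k >= 2, n_permutations >= 1
    )
  })
  structure(cfg, class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Unspecified fields fall back to the [run_config()] defaults; unknown
#' fields are an error so typos do not pass silently.
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, vals)
}
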