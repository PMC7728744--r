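#' Seed-DEG selection, network expansion and enrichment for one comparison
#'
#' The workflow's core chain: fit the moderated t for a comparison, take
#' seed DEGs through the strict gate (`fc_seed`, `p_seed`), expand them
#' over the PPI network at the relaxed gate (`fc_expand`), and run
#' pathway enrichment for both the seed and the expanded list. The
#' enrichment universe is the measured genes intersected with the
#' gene-set universe, and query lists are restricted to it.
#'
#' @param expr an `ExpressionMatrix` on the analysis scale.
#' @param meta a `SampleTable`.
#' @param network an `igraph` PPI network.
#' @param gene_sets a `GeneSetDB`.
#' @param comparison a resolved `ComparisonSpec`, or the name of one of
#'   the [standard_comparisons()].
#' @param cfg a `RunConfig`.
#' @return list: `comparison`, `dge` (the `DGETable`), `seeds`,
#'   `expansion` (`ExpansionResult`), `universe`,
#'   `enrichment_seeds`, `enrichment_expanded` (`EnrichmentTable`s; NULL
#'   when the corresponding query is empty in the universe).
#' @export
dge_expand_enrich <- function(expr, meta, network, gene_sets, comparison,
                              cfg = run_config()) {
  cmp <- if (inherits(comparison, "ComparisonSpec")) comparison else {
    cmps <- standard_comparisons(meta)
    if (!comparison %in% names(cmps)) {
      stop("unknown comparison '", comparison, "'; presets: ",
           paste(names(cmps), collapse = ", "))
    }
    cmps[[comparison]]
  }
  tbl <- moderated_t(expr, cmp)
  seeds <- select_degs(tbl, deg_criteria(cfg$fc_seed, cfg$p_seed))
  expansion <- expand_by_ppi(seeds, tbl, network, cfg$fc_expand,
                             cfg$expansion_mode)
  universe <- intersect(rownames(expr), gene_sets$universe)
  run_enrich <- function(genes) {
    q <- intersect(genes, universe)
    if (length(q) == 0L) return(NULL)
    enrich(q, gene_sets, universe, cfg$fdr_alpha)
  }
  list(
    comparison = cmp$name,
    dge = tbl,
    seeds = seeds,
    expansion = expansion,
    universe = universe,
    enrichment_seeds = run_enrich(seeds),
    enrichment_expanded = run_enrich(expansion$expanded)
  )
}
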