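# Independent oracles and fixture builders used across the suite.

# Exact upper-tail overlap probability by enumerating every possible draw
# of |b| elements from the universe (feasible for |universe| <= 12).
brute_force_overlap_p <- function(list_a, list_b, universe) {
  N <- length(universe)
  n <- length(list_b)
  k_obs <- length(intersect(list_a, list_b))
  if (k_obs == 0) return(1)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2, function(s) length(intersect(s, list_a)) >= k_obs)
  mean(hits)
}

# Tiny log-scale expression matrix with explicit values
tiny_expr <- function(values, genes, samples, scale = "log2_tpm1") {
  expression_matrix(
    matrix(values, length(genes), length(samples),
           dimnames = list(genes, samples), byrow = TRUE),
    scale
  )
}

# Minimal two-arm, two-timepoint metadata table
tiny_meta <- function(n_per_group = 2) {
  cfg <- synth_config(n_patients_per_arm = 2 * n_per_group,
                      responder_fraction = c(TNFi = 0.5, IL17Ai = 0.5),
                      rng_seed = 1L)
  simulate_cohort(cfg)$meta
}

# A DGETable-shaped frame from explicit fc/p values
fake_dge <- function(genes, fc_signed, p) {
  structure(
    data.frame(gene = genes,
               log2fc = ifelse(fc_signed >= 0, log2(pmax(fc_signed, 1)),
                               -log2(pmax(-fc_signed, 1))),
               fc_signed = fc_signed, s2 = 1, s2_post = 1, t = 0,
               df = 10, p = p, stringsAsFactors = FALSE),
    class = c("DGETable", "data.frame")
  )
}

# Study config for the planted-pathway benchmark: 1000 genes, 50 pathways
# of 40 genes, one pathway with 20 genes shifted by delta in the group-1
# samples of the IL-17Ai responder-vs-nonresponder baseline comparison,
# sigma = 0.5, 10 samples per group, modular PPI (0.3 within / 0.01
# background).
planted_benchmark_config <- function(seed, delta = 1.0, n_affected = 20,
                                     pathway_size = 40,
                                     comparison = "IL17Ai_R_vs_NR_baseline") {
  synth_config(
    n_genes = 1000, n_pathways = 50,
    pathway_size_range = c(pathway_size, pathway_size),
    n_patients_per_arm = 20,
    responder_fraction = c(TNFi = 0.5, IL17Ai = 0.5),
    planted_pathways = list(list(pathway = 1, comparison = comparison,
                                 n_affected = n_affected, delta = delta)),
    noise_sd = 0.5, rng_seed = seed
  )
}
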