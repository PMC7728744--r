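#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study the rest of the analysis runs on.
#
# The cohort mirrors the target study design: two biologic arms (TNFi,
# IL-17Ai) of 20 patients each, sampled at baseline and month 3, with
# responder fractions 0.65 / 0.35. Two pathway-level effects are planted:
#  - a RHO-GTPase family pathway shifted in IL-17Ai responders at baseline
#    (the signal the downstream network analysis should recover), and
#  - a JAK/STAT-named pathway shifted in TNFi responders at baseline
#    (so the key-term comparison has an arm-specific counterpart).
# Expression is drawn on the log2(TPM+1) scale with sd 0.5 noise and a
# two-batch shift, over 1000 genes and 50 pathways of 40 genes.

suppressPackageStartupMessages(library(degnet))

out_dir <- "results/data"
cfg <- synth_config(
  n_genes = 1000, n_pathways = 50, pathway_size_range = c(40, 40),
  n_patients_per_arm = 20,
  responder_fraction = c(TNFi = 0.65, IL17Ai = 0.35),
  planted_pathways = list(
    list(pathway = 1, comparison = "IL17Ai_R_vs_NR_baseline",
         n_affected = 20, delta = 1.2),
    list(pathway = 21, comparison = "TNFi_R_vs_NR_baseline",
         n_affected = 20, delta = 1.2)
  ),
  noise_sd = 0.5,
  batch_effect = list(n_batches = 2, shift_sd = 0.3),
  rng_seed = 20260901L
)

study <- simulate_study(cfg)
write_study(study, out_dir)

message("wrote synthetic study to ", out_dir)
message(sprintf("  %d genes x %d samples, %d pathways, %d PPI edges",
                nrow(study$expr), ncol(study$expr),
                length(study$gene_sets$sets),
                nrow(ppi_edges(study$network))))
for (pl in study$truth$planted) {
  message(sprintf("  planted: %d genes of '%s' shifted by +%.1f in %s",
                  length(pl$genes), pl$pathway, pl$delta, pl$comparison))
}
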