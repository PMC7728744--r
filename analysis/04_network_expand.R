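#!/usr/bin/env Rscript
# Stage 4: overlap statistics between baseline DEG lists, and PPI-guided
# expansion of the two responder-vs-nonresponder seed lists.
#
# The seed lists of the three baseline comparisons are compared pairwise
# (hypergeometric + randomization test over the measured genes), then
# each responder-vs-nonresponder seed list is expanded one hop over the
# PPI network at the relaxed gate |FC| >= 1.2.

suppressPackageStartupMessages(library(degnet))

expr <- read_expression("results/expression_adjusted.tsv", "log2_tpm1")
net <- read_ppi("results/data/ppi.tsv")
cfg <- run_config(rng_seed = 20260901L)
universe <- rownames(expr)

baseline <- c("TNFi_R_vs_NR_baseline", "IL17Ai_R_vs_NR_baseline",
              "TNFi_R_vs_IL17Ai_R_baseline")
seeds <- lapply(baseline, function(nm) {
  readLines(sprintf("results/dge/%s_seeds.txt", nm))
})
names(seeds) <- baseline

dir.create("results/network", showWarnings = FALSE, recursive = TRUE)
ov_rows <- list()
for (i in 1:(length(baseline) - 1)) {
  for (j in (i + 1):length(baseline)) {
    ov <- randomization_overlap(seeds[[i]], seeds[[j]], universe,
                                B = cfg$n_permutations, seed = cfg$rng_seed)
    ov_rows[[length(ov_rows) + 1]] <- data.frame(
      list_a = baseline[i], list_b = baseline[j],
      N = ov$N, K = ov$K, n = ov$n, k = ov$k,
      p_hypergeom = ov$p_hypergeom, p_randomization = ov$p_randomization
    )
    message(sprintf("%s vs %s: overlap %d (hypergeom p = %.3g, randomization p = %.3g)",
                    baseline[i], baseline[j], ov$k, ov$p_hypergeom,
                    ov$p_randomization))
  }
}
write.table(do.call(rbind, ov_rows), "results/network/seed_overlaps.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (nm in c("TNFi_R_vs_NR_baseline", "IL17Ai_R_vs_NR_baseline")) {
  tbl <- utils::read.delim(sprintf("results/dge/%s.tsv", nm))
  class(tbl) <- c("DGETable", "data.frame")
  ex <- expand_by_ppi(seeds[[nm]], tbl, net, cfg$fc_expand,
                      cfg$expansion_mode)
  write_expansion(ex, tbl, sprintf("results/network/%s", nm))
  writeLines(ex$expanded, sprintf("results/network/%s_expanded.txt", nm))
  message(sprintf("%s: %d seeds expanded to %d genes (%d qualifying edges)",
                  nm, length(ex$seeds), length(ex$expanded),
                  nrow(ex$qualifying_edges)))
}
message("wrote overlap stats and expansions under results/network/")
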