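#!/usr/bin/env Rscript
# Stage 5: pathway enrichment of the expanded DEG lists and the key-term
# view of the enriched-pathway titles.
#
# Each expanded list is tested against all 50 pathways (hypergeometric,
# BH-FDR over the measured-gene universe); key terms are weighted by the
# best enrichment p among the titles containing them, and the term sets
# of the two arms are differenced to expose arm-specific themes.

suppressPackageStartupMessages(library(degnet))

expr <- read_expression("results/expression_adjusted.tsv", "log2_tpm1")
gs <- read_gmt("results/data/pathways.gmt")
cfg <- run_config()
universe <- intersect(rownames(expr), gs$universe)

dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
tabs <- list()
for (nm in c("TNFi_R_vs_NR_baseline", "IL17Ai_R_vs_NR_baseline")) {
  query <- intersect(readLines(sprintf("results/network/%s_expanded.txt", nm)),
                     universe)
  res <- enrich(query, gs, universe, cfg$fdr_alpha)
  tabs[[nm]] <- res
  write.table(res, sprintf("results/enrichment/%s_pathways.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tw <- key_terms(res, cfg$fdr_alpha)
  write.table(tw, sprintf("results/enrichment/%s_terms.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d/%d pathways enriched at q <= %.2f; top: %s (q = %.2g)",
                  nm, sum(res$enriched), nrow(res), cfg$fdr_alpha,
                  res$pathway[1], res$q[1]))
}

diff <- differential_terms(tabs[["TNFi_R_vs_NR_baseline"]],
                           tabs[["IL17Ai_R_vs_NR_baseline"]],
                           cfg$fdr_alpha)
message("terms specific to the TNFi comparison:    ",
        paste(diff$a_specific, collapse = ", "))
message("terms specific to the IL-17Ai comparison: ",
        paste(diff$b_specific, collapse = ", "))
writeLines(c("tnfi_specific\til17ai_specific",
             paste(paste(diff$a_specific, collapse = ","),
                   paste(diff$b_specific, collapse = ","), sep = "\t")),
           "results/enrichment/differential_terms.tsv")
message("wrote enrichment tables under results/enrichment/")
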