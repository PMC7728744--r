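test_that("simulation is fully reproducible under a fixed seed", {
  cfg <- synth_config(n_genes = 100, n_pathways = 5, n_patients_per_arm = 4,
                      rng_seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(unclass(s1$expr), unclass(s2$expr))
  expect_identical(s1$meta, s2$meta)
  expect_identical(ppi_edges(s1$network), ppi_edges(s2$network))
  expect_identical(s1$gene_sets$sets, s2$gene_sets$sets)

  s3 <- simulate_study(synth_config(n_genes = 100, n_pathways = 5,
                                    n_patients_per_arm = 4, rng_seed = 100))
  expect_false(identical(unclass(s1$expr), unclass(s3$expr)))
})

test_that("cohort design matches the configured arms and fractions", {
  cfg <- synth_config(n_genes = 50, n_pathways = 3, n_patients_per_arm = 20,
                      responder_fraction = c(TNFi = 0.65, IL17Ai = 0.35),
                      rng_seed = 5)
  meta <- simulate_cohort(cfg)$meta
  expect_equal(nrow(meta), 80L)  # 2 arms x 20 patients x 2 timepoints
  tnfi_resp <- unique(meta$patient_id[meta$arm == "TNFi" &
                                        meta$response == "responder"])
  il_resp <- unique(meta$patient_id[meta$arm == "IL17Ai" &
                                      meta$response == "responder"])
  expect_length(tnfi_resp, 13L)
  expect_length(il_resp, 7L)
  expect_true(all(table(meta$patient_id) == 2))
})

test_that("a null simulation yields uniform p-values", {
  cfg <- synth_config(n_genes = 20000, n_pathways = 5,
                      n_patients_per_arm = 10,
                      responder_fraction = c(TNFi = 0.5, IL17Ai = 0.5),
                      rng_seed = 7)
  co <- simulate_cohort(cfg)
  cmp <- standard_comparisons(co$meta)[["TNFi_R_vs_NR_baseline"]]
  tbl <- moderated_t(co$expr, cmp)
  ks <- suppressWarnings(stats::ks.test(tbl$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("a dominant planted gene attains the smallest p in its comparison", {
  for (s in 1:20) {
    cfg <- synth_config(n_genes = 200, n_pathways = 3,
                        pathway_size_range = c(5, 5),
                        n_patients_per_arm = 10,
                        responder_fraction = c(TNFi = 0.5, IL17Ai = 0.5),
                        planted_pathways = list(list(
                          pathway = 1, comparison = "TNFi_R_vs_NR_baseline",
                          n_affected = 1, delta = 3)),
                        noise_sd = 0.1, rng_seed = 300 + s)
    co <- simulate_cohort(cfg)
    cmp <- standard_comparisons(co$meta)[["TNFi_R_vs_NR_baseline"]]
    tbl <- moderated_t(co$expr, cmp)
    expect_equal(tbl$gene[which.min(tbl$p)], co$truth$planted[[1]]$genes)
  }
})

test_that("null genes pass the seed gate at no more than the nominal rate", {
  # delta = 0 everywhere: the seed criteria's p gate dominates, so the
  # fraction selected must stay below alpha plus sampling noise
  rates <- vapply(1:5, function(s) {
    cfg <- synth_config(n_genes = 5000, n_pathways = 3,
                        n_patients_per_arm = 10,
                        responder_fraction = c(TNFi = 0.5, IL17Ai = 0.5),
                        rng_seed = 400 + s)
    co <- simulate_cohort(cfg)
    cmp <- standard_comparisons(co$meta)[["TNFi_R_vs_NR_baseline"]]
    tbl <- moderated_t(co$expr, cmp)
    length(select_degs(tbl, deg_criteria(1, 0.05))) / nrow(tbl)
  }, numeric(1))
  expect_lte(mean(rates), 0.05 + 3 * sqrt(0.05 * 0.95 / (5 * 5000)))
})

test_that("planted effects reach the seed gate with high power", {
  # delta = 1.0, sigma = 0.5, 10 samples per group
  hit <- vapply(1:20, function(s) {
    cfg <- planted_benchmark_config(500 + s)
    co <- simulate_cohort(cfg)
    cmp <- standard_comparisons(co$meta)[["IL17Ai_R_vs_NR_baseline"]]
    tbl <- moderated_t(co$expr, cmp)
    degs <- select_degs(tbl, deg_criteria(1.4, 0.05))
    mean(co$truth$planted[[1]]$genes %in% degs)
  }, numeric(1))
  expect_gte(mean(hit), 0.90)
})

test_that("the simulated PPI network is pathway-modular", {
  base <- list(n_genes = 120, n_pathways = 4, pathway_size_range = c(20, 20),
               n_patients_per_arm = 2)
  # extremes: cliques and empty graph
  cfg1 <- do.call(synth_config, c(base, ppi_within_pathway_prob = 1,
                                  ppi_background_prob = 0, rng_seed = 1))
  gs1 <- simulate_gene_sets(cfg1)
  net1 <- simulate_network(cfg1, gs1)
  for (s in gs1$sets) {
    sub <- igraph::induced_subgraph(net1, s)
    expect_equal(igraph::ecount(sub), choose(length(s), 2))
  }
  cfg0 <- do.call(synth_config, c(base, ppi_within_pathway_prob = 0,
                                  ppi_background_prob = 0, rng_seed = 1))
  expect_equal(nrow(ppi_edges(simulate_network(cfg0, gs1))), 0L)

  # modularity: mean within-pathway degree exceeds background degree
  diffs <- vapply(1:10, function(s) {
    cfg <- synth_config(n_genes = 300, n_pathways = 5,
                        pathway_size_range = c(30, 30), n_patients_per_arm = 2,
                        ppi_within_pathway_prob = 0.3,
                        ppi_background_prob = 0.01, rng_seed = 600 + s)
    gs <- simulate_gene_sets(cfg)
    net <- simulate_network(cfg, gs)
    in_pw <- unique(unlist(gs$sets))
    deg <- igraph::degree(net)
    within_deg <- mean(vapply(gs$sets, function(s2) {
      mean(igraph::ecount(igraph::induced_subgraph(net, s2))) * 2 / length(s2)
    }, numeric(1)))
    bg <- setdiff(igraph::V(net)$name, in_pw)
    within_deg - mean(deg[bg])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("written study files re-read into valid, identical objects", {
  cfg <- synth_config(n_genes = 80, n_pathways = 4, n_patients_per_arm = 3,
                      responder_fraction = c(TNFi = 0.7, IL17Ai = 0.3),
                      planted_pathways = list(list(
                        pathway = 2, comparison = "TNFi_R_vs_NR_baseline",
                        n_affected = 3, delta = 1.5)),
                      batch_effect = list(n_batches = 2, shift_sd = 0.3),
                      rng_seed = 77)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"), "log2_tpm1")
  meta <- read_sample_table(file.path(dir, "metadata.tsv"))
  net <- read_ppi(file.path(dir, "ppi.tsv"))
  gs <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(unclass(expr), unclass(st$expr), tolerance = 1e-12)
  expect_equal(as.data.frame(meta), as.data.frame(st$meta))
  expect_identical(ppi_edges(net), ppi_edges(st$network))
  expect_identical(gs$sets, st$gene_sets$sets)
  check_samples_resolve(expr, meta)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$gene, st$truth$planted[[1]]$genes)
})
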