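make_cmp <- function(m, g1, g2, name = "test") {
  cmp <- comparison_spec(name, list(), list())
  cmp$g1_samples <- g1
  cmp$g2_samples <- g2
  cmp
}

test_that("fold change is group1 minus group2 with signed linear mapping", {
  m <- tiny_expr(c(3, 3, 2, 2,
                   2, 2, 3, 3,
                   4.485, 4.485, 4, 4),
                 c("up", "down", "edge"), c("a1", "a2", "b1", "b2"))
  cmp <- make_cmp(m, c("a1", "a2"), c("b1", "b2"))
  fc <- compute_fold_change(m, cmp)
  expect_equal(fc$log2fc, c(1, -1, 0.485))
  expect_equal(fc$fc_signed[1:2], c(2, -2))
  expect_equal(fc$fc_signed[3], 1.3997, tolerance = 1e-4)

  # antisymmetry under group swap
  rev_fc <- compute_fold_change(m, make_cmp(m, c("b1", "b2"), c("a1", "a2")))
  expect_equal(rev_fc$log2fc, -fc$log2fc)
  expect_equal(signed_fc(0), 1)
})

test_that("moderation estimation handles degenerate and simulated priors", {
  expect_error(estimate_moderation(rep(0, 20), 4), "all variances are zero")
  expect_error(estimate_moderation(rep(1, 9), 4), "at least 10")

  eq <- estimate_moderation(rep(0.3, 50), 4)
  expect_identical(eq$d0, Inf)
  expect_equal(eq$s0_sq, 0.3)

  # known-truth simulation: variance prior d0 = 4, s0_sq = 0.16, with the
  # chi-square sampling layer at df = 8, 20000 genes
  set.seed(42)
  df <- 8
  sig2 <- 0.16 * 4 / rchisq(20000, 4)
  s2 <- sig2 * rchisq(20000, df) / df
  mp <- estimate_moderation(s2, df)
  expect_equal(mp$d0, 4, tolerance = 0.15)
  expect_equal(mp$s0_sq, 0.16, tolerance = 0.05)
})

test_that("moderation estimates agree with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(9)
  s2 <- 0.25 * 5 / rchisq(5000, 5) * rchisq(5000, 6) / 6
  mp <- estimate_moderation(s2, 6)
  sv <- limma::squeezeVar(s2, 6)
  expect_equal(mp$d0, sv$df.prior, tolerance = 1e-8)
  expect_equal(mp$s0_sq, sv$var.prior, tolerance = 1e-8)
})

test_that("moderated t follows the stated formula and reduces to classical t", {
  # hand-constructed gene: n1 = n2 = 3, log2fc = 1, pooled s2 = 0.25
  m <- tiny_expr(c(4.5, 5, 5.5, 3.5, 4, 4.5), "g1",
                 c("a1", "a2", "a3", "b1", "b2", "b3"))
  cmp <- make_cmp(m, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  tbl <- moderated_t(m, cmp, moderation_params(4, 0.16))
  expect_equal(tbl$log2fc, 1)
  expect_equal(tbl$s2, 0.25)
  expect_equal(tbl$s2_post, 0.205)
  expect_equal(tbl$t, 1 / sqrt(0.205 * (2 / 3)), tolerance = 1e-12)
  expect_equal(tbl$df, 8)

  # d0 = 0 equals the classical pooled two-sample t
  set.seed(3)
  v <- matrix(rnorm(50 * 7), 50, 7,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("s%d", 1:7)))
  m2 <- expression_matrix(v, "log2_tpm1")
  cmp2 <- make_cmp(m2, c("s1", "s2", "s3"), c("s4", "s5", "s6", "s7"))
  tbl2 <- moderated_t(m2, cmp2, moderation_params(0, 1))
  for (g in c(1, 17, 50)) {
    tt <- t.test(v[g, 1:3], v[g, 4:7], var.equal = TRUE)
    expect_equal(tbl2$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tbl2$p[g], tt$p.value, tolerance = 1e-12)
    expect_equal(tbl2$df[g], 5)
  }

  # degenerate gene with identical groups: no NaN, p = 1
  v[1, ] <- 2
  m3 <- expression_matrix(v, "log2_tpm1")
  tbl3 <- moderated_t(m3, cmp2, moderation_params(0, 1))
  expect_equal(tbl3$t[1], 0)
  expect_equal(tbl3$p[1], 1)

  expect_error(moderated_t(m2, make_cmp(m2, "s1", c("s2", "s3"))), ">= 2")
})

test_that("paired moderated t uses within-pair differences", {
  m <- tiny_expr(c(2, 3, 4, 1, 1, 2), "g1",
                 c("p1_a", "p2_a", "p3_a", "p1_b", "p2_b", "p3_b"))
  cmp <- make_cmp(m, c("p1_a", "p2_a", "p3_a"), c("p1_b", "p2_b", "p3_b"))
  cmp$paired <- TRUE
  tbl <- moderated_t(m, cmp, moderation_params(0, 1))
  tt <- t.test(c(2, 3, 4), c(1, 1, 2), paired = TRUE)
  expect_equal(tbl$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(tbl$p, tt$p.value, tolerance = 1e-12)
  expect_equal(tbl$df, 2)
})

test_that("group swap negates t and preserves p; moderation is a contraction", {
  set.seed(5)
  v <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("s%d", 1:8)))
  m <- expression_matrix(v, "log2_tpm1")
  cmp <- make_cmp(m, paste0("s", 1:4), paste0("s", 5:8))
  rev <- make_cmp(m, paste0("s", 5:8), paste0("s", 1:4))
  a <- moderated_t(m, cmp)
  prm <- moderation_params(attr(a, "d0"), attr(a, "s0_sq"))
  b <- moderated_t(m, rev, prm)
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$t, -a$t)
  expect_equal(b$p, a$p)
  expect_true(all(a$s2_post >= pmin(a$s2, prm$s0_sq) - 1e-12))
  expect_true(all(a$s2_post <= pmax(a$s2, prm$s0_sq) + 1e-12))
})

test_that("null p-values are approximately uniform at 20000 genes", {
  set.seed(101)
  ng <- 20000
  sig <- sqrt(0.16 * 4 / rchisq(ng, 4))
  v <- matrix(rnorm(ng * 20, 0, rep(sig, 20)), ng, 20,
              dimnames = list(sprintf("G%05d", 1:ng), sprintf("s%02d", 1:20)))
  m <- expression_matrix(v + 5, "log2_tpm1")
  cmp <- make_cmp(m, sprintf("s%02d", 1:10), sprintf("s%02d", 11:20))
  tbl <- moderated_t(m, cmp)
  ks <- suppressWarnings(stats::ks.test(tbl$p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("DEG selection applies gates and deterministic ordering", {
  tbl <- fake_dge(
    c("g_strong", "g_fc_low", "g_nop", "g_down", "g_tie_a", "g_tie_b"),
    c(1.5, 1.3, 1.45, -1.25, 1.6, 1.7),
    c(0.01, 0.001, 0.20, 0.5, 0.02, 0.02)
  )
  strict <- deg_criteria(1.4, 0.05, TRUE)
  sel <- select_degs(tbl, strict)
  expect_true("g_strong" %in% sel)
  expect_false("g_fc_low" %in% sel)   # fails FC gate despite tiny p
  expect_false("g_nop" %in% sel)      # fails p gate

  relaxed <- deg_criteria(1.2, require_p = FALSE)
  expect_true("g_down" %in% select_degs(tbl, relaxed))

  # ordering: p ascending, tie by larger |FC|, then symbol
  expect_equal(sel, c("g_strong", "g_tie_b", "g_tie_a"))

  # monotone in thresholds: relaxing never removes a gene
  for (fc in c(1.2, 1.4, 1.6)) {
    for (p in c(0.01, 0.05, 0.2)) {
      tight <- select_degs(tbl, deg_criteria(fc, p))
      loose <- select_degs(tbl, deg_criteria(fc - 0.1, min(p * 2, 1)))
      expect_true(all(tight %in% loose))
    }
  }
})

test_that("top_k_by_p truncates the DEG ranking and warns when short", {
  set.seed(13)
  n <- 250
  tbl <- fake_dge(sprintf("G%03d", 1:n),
                  sample(c(-1, 1), n, TRUE) * runif(n, 1.4, 3),
                  runif(n, 0, 0.04))
  crit <- deg_criteria(1.4, 0.05)
  top <- top_k_by_p(tbl, crit, 100)
  expect_length(top, 100L)
  expect_equal(top, select_degs(tbl, crit)[1:100])
  # the 100 smallest p-values exactly
  expect_setequal(top, tbl$gene[order(tbl$p)][1:100])

  few <- fake_dge(sprintf("G%d", 1:30), rep(2, 30), rep(0.01, 30))
  expect_warning(res <- top_k_by_p(few, crit, 100), "only 30")
  expect_length(res, 30L)
})

test_that("the seven preset comparisons resolve on a full cohort", {
  meta <- tiny_meta(3)
  cmps <- standard_comparisons(meta)
  expect_length(cmps, 7L)
  for (cmp in cmps) {
    expect_gt(length(cmp$g1_samples), 0)
    expect_gt(length(cmp$g2_samples), 0)
    expect_length(intersect(cmp$g1_samples, cmp$g2_samples), 0L)
  }
  # baseline responder-vs-nonresponder specs are within-arm and disjoint
  b <- cmps[["TNFi_R_vs_NR_baseline"]]
  arms <- meta$arm[match(c(b$g1_samples, b$g2_samples), meta$sample_id)]
  expect_true(all(arms == "TNFi"))

  no_m3 <- sample_table(as.data.frame(meta)[meta$timepoint == "baseline", ])
  expect_error(standard_comparisons(no_m3), "month3|selects no samples")

  paired <- standard_comparisons(meta, paired_prepost = TRUE)
  pc <- paired[["TNFi_R_baseline_vs_month3"]]
  expect_true(pc$paired)
  p1 <- meta$patient_id[match(pc$g1_samples, meta$sample_id)]
  p2 <- meta$patient_id[match(pc$g2_samples, meta$sample_id)]
  expect_identical(p1, p2)
})
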