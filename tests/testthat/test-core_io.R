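test_that("expression matrix TSV round-trips and validates identifiers", {
  m <- tiny_expr(c(1, 2, 3, 4, 5, 6), c("A", "B", "C"), c("s1", "s2"), "tpm")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  m2 <- read_expression(path, "tpm")
  expect_equal(dim(m2), c(3L, 2L))
  expect_equal(unclass(m2), unclass(m), ignore_attr = TRUE)
  expect_identical(em_scale(m2), "tpm")

  dup <- matrix(1, 2, 2, dimnames = list(c("A", "A"), c("s1", "s2")))
  expect_error(expression_matrix(dup, "tpm"), "duplicate gene")
  expect_error(
    expression_matrix(matrix(c(1, NA), 1, 2,
                             dimnames = list("A", c("s1", "s2"))), "tpm"),
    "non-finite"
  )
})

test_that("read_expression rejects duplicate samples and non-numeric cells", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts1", "A\t1\t2"), path)
  expect_error(read_expression(path, "tpm"), "s1")

  writeLines(c("gene\ts1\ts2", "A\t1\toops"), path)
  expect_error(read_expression(path, "tpm"), "oops")
})

test_that("duplicate gene rows collapse to the max-total-signal row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t8\t2", "A\t3\t1", "B\t1\t1"), path)
  expect_warning(m <- read_expression(path, "tpm"), "collapsed")
  expect_equal(nrow(m), 2L)
  expect_equal(unname(unclass(m)["A", ]), c(8, 2))
})

test_that("read_ppi deduplicates pairs and drops self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol1\tsymbol2", "A\tB", "B\tA", "C\tC", "A\tB"), path)
  net <- suppressMessages(read_ppi(path))
  expect_equal(nrow(ppi_edges(net)), 1L)
  expect_equal(unname(ppi_edges(net)[1, ]), c("A", "B"))

  writeLines(c("symbol1\tsymbol2", "A\tB", "B\tC"), path)
  net2 <- read_ppi(path)
  expect_setequal(ppi_nodes(net2), c("A", "B", "C"))
  expect_equal(nrow(ppi_edges(net2)), 2L)

  writeLines("symbol1\tsymbol2", path)
  expect_equal(nrow(ppi_edges(read_ppi(path))), 0L)

  writeLines(c("x\ty", "A\tB"), path)
  expect_error(read_ppi(path), "available: x, y")
})

test_that("PPI networks round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  net <- ppi_network(cbind(c("B", "A", "C"), c("C", "B", "D")))
  write_ppi(net, path)
  net2 <- read_ppi(path)
  expect_identical(ppi_edges(net2), ppi_edges(net))
  expect_identical(ppi_nodes(net2), ppi_nodes(net))
})

test_that("random edge lists always yield simple undirected graphs", {
  set.seed(7)
  syms <- LETTERS[1:8]
  for (i in 1:20) {
    el <- cbind(sample(syms, 30, replace = TRUE),
                sample(syms, 30, replace = TRUE))
    net <- suppressMessages(ppi_network(el))
    ed <- ppi_edges(net)
    expect_false(any(ed[, 1] == ed[, 2]))
    expect_false(anyDuplicated(paste(ed[, 1], ed[, 2])) > 0)
    expect_true(all(as.vector(ed) %in% ppi_nodes(net)))
  }
})

test_that("GMT files parse, deduplicate members and report bad lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\tA\tB\tC", "set2\tdesc\tB\tD\tD"), path)
  db <- read_gmt(path)
  expect_setequal(db$universe, c("A", "B", "C", "D"))
  expect_equal(db$sets$set2, c("B", "D"))

  writeLines(c("set1\tdesc\tA", "broken\tdesc"), path)
  expect_error(read_gmt(path), "line 2")

  db3 <- read_gmt({
    writeLines("s\td\tA\tB", path)
    path
  })
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db3, p2)
  expect_equal(read_gmt(p2)$sets, db3$sets)
})

test_that("a 16-set family with a 485-gene union reads back at size 485", {
  # synthetic family built to the reference shape: 16 pathways, 485
  # unique proteins in their union
  prot <- sprintf("P%03d", 1:485)
  sets <- lapply(1:16, function(i) {
    idx <- (((i - 1) * 31) %% 485) + seq_len(40)
    prot[((idx - 1) %% 485) + 1]
  })
  names(sets) <- sprintf("RHO-GTPase pathway %02d", 1:16)
  expect_setequal(unique(unlist(sets)), prot)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gene_set_db(sets), path)
  db <- read_gmt(path)
  expect_length(db$sets, 16L)
  expect_length(db$universe, 485L)
})

test_that("keyword retrieval normalizes case and separators", {
  db <- gene_set_db(list(
    "RHO GTPase cycle" = c("A", "B"),
    "Signaling by Rho-GTPases" = c("B", "C"),
    "TNF signaling" = c("D", "E")
  ))
  hit <- retrieve_sets_by_keyword(db, "rho-gtpase")
  expect_setequal(names(hit$sets), c("RHO GTPase cycle", "Signaling by Rho-GTPases"))
  expect_identical(hit$universe, db$universe)

  expect_length(suppressMessages(retrieve_sets_by_keyword(db, "zzz"))$sets, 0L)
  expect_true("TNF signaling" %in%
                names(retrieve_sets_by_keyword(db, "TNF signaling")$sets))

  # retrieval is always a sub-collection of the input
  for (kw in c("rho", "signaling", "cycle", "gtp", "q")) {
    sub <- suppressMessages(retrieve_sets_by_keyword(db, kw))
    expect_true(all(names(sub$sets) %in% names(db$sets)))
  }
})

test_that("sample tables validate design constraints", {
  meta <- tiny_meta()
  expect_s3_class(meta, "SampleTable")
  bad <- as.data.frame(meta)
  bad$timepoint[2] <- bad$timepoint[1]
  expect_error(sample_table(bad), "one sample per timepoint")
  bad2 <- as.data.frame(meta)
  bad2$arm[1] <- "steroids"
  expect_error(sample_table(bad2), "invalid arm")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(meta, path)
  expect_equal(as.data.frame(read_sample_table(path)), as.data.frame(meta))
})

test_that("run configs validate thresholds and read from YAML", {
  cfg <- run_config()
  expect_equal(cfg$fc_seed, 1.4)
  expect_equal(cfg$fc_expand, 1.2)
  expect_equal(cfg$top_k, 100L)
  expect_error(run_config(fc_member_lo = 1.5, fc_member_hi = 1.4))
  expect_error(run_config(p_seed = 0))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fc_seed: 1.5", "top_k: 50", "rng_seed: 7"), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$fc_seed, 1.5)
  expect_equal(cfg2$top_k, 50L)
  writeLines("not_a_field: 1", path)
  expect_error(read_run_config(path), "unknown config field")
})
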