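#' Configuration for the synthetic study generator
#'
#' Describes a two-arm, two-timepoint responder/non-responder cohort with
#' differential signal planted into pathway modules, plus a matched
#' modular PPI network and pathway collection. Defaults mirror the study
#' design the pipeline targets: 20 patients per biologic arm sampled at
#' baseline and month 3, responder fractions 0.65 (TNFi) and 0.35
#' (IL-17Ai), Gaussian noise with sd 0.5 on the log2 scale, and a
#' 16-pathway keyword family inside a 50-pathway collection over 1000
#' genes.
#'
#' @param n_genes number of genes.
#' @param n_pathways number of pathways in the collection.
#' @param pathway_size_range inclusive (min, max) pathway sizes.
#' @param n_patients_per_arm patients per biologic arm.
#' @param responder_fraction named fractions for arms `TNFi` and `IL17Ai`.
#' @param planted_pathways list of planted effects, each a list with
#'   `pathway` (index or name), `comparison` (a [standard_comparisons()]
#'   name), `n_affected` (genes shifted) and `delta` (log2 mean shift
#'   added to the comparison's group-1 samples).
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param baseline_mean_range uniform range of per-gene baseline means
#'   (log2 scale).
#' @param ppi_within_pathway_prob edge probability for gene pairs sharing
#'   a pathway.
#' @param ppi_background_prob edge probability for all other pairs.
#' @param batch_effect optional list `(n_batches, shift_sd)` adding
#'   per-gene, per-batch Gaussian shifts.
#' @param family_keyword keyword carried by the pathway-family names (to
#'   exercise keyword retrieval).
#' @param n_family_pathways number of pathways named with the keyword.
#' @param rng_seed integer seed; all outputs are reproducible given it.
#' @return a validated `SynthConfig` list.
#' @export
synth_config <- function(n_genes = 1000, n_pathways = 50,
                         pathway_size_range = c(10, 40),
                         n_patients_per_arm = 20,
                         responder_fraction = c(TNFi = 0.65, IL17Ai = 0.35),
                         planted_pathways = list(),
                         noise_sd = 0.5,
                         baseline_mean_range = c(2, 8),
                         ppi_within_pathway_prob = 0.3,
                         ppi_background_prob = 0.01,
                         batch_effect = NULL,
                         family_keyword = "RHO-GTPase",
                         n_family_pathways = 16,
                         rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_patients_per_arm = as.integer(n_patients_per_arm),
    responder_fraction = responder_fraction,
    planted_pathways = planted_pathways,
    noise_sd = noise_sd, baseline_mean_range = baseline_mean_range,
    ppi_within_pathway_prob = ppi_within_pathway_prob,
    ppi_background_prob = ppi_background_prob,
    batch_effect = batch_effect,
    family_keyword = family_keyword,
    n_family_pathways = as.integer(min(n_family_pathways, n_pathways)),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$n_genes >= 10, cfg$n_pathways >= 1,
    length(cfg$pathway_size_range) == 2,
    cfg$pathway_size_range[1] >= 2,
    cfg$pathway_size_range[2] >= cfg$pathway_size_range[1],
    cfg$pathway_size_range[2] <= cfg$n_genes,
    cfg$n_patients_per_arm >= 2,
    all(c("TNFi", "IL17Ai") %in% names(cfg$responder_fraction)),
    all(cfg$responder_fraction >= 0 & cfg$responder_fraction <= 1),
    cfg$noise_sd > 0,
    cfg$ppi_within_pathway_prob >= 0, cfg$ppi_within_pathway_prob <= 1,
    cfg$ppi_background_prob >= 0, cfg$ppi_background_prob <= 1
  )
  for (pl in cfg$planted_pathways) {
    stopifnot(all(c("pathway", "comparison", "n_affected", "delta") %in% names(pl)),
              is.finite(pl$delta), pl$n_affected >= 1)
  }
  structure(cfg, class = "SynthConfig")
}

.synth_genes <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

#' Simulate a pathway collection
#'
#' Pathway sizes are uniform in the configured range; members are sampled
#' without replacement per pathway (overlap across pathways is allowed).
#' The first `n_family_pathways` names carry the family keyword so that
#' keyword retrieval can be exercised; the remainder cycle through a
#' small vocabulary of signaling themes.
#'
#' @param cfg a `SynthConfig`.
#' @return a `GeneSetDB` whose universe is the union of members.
#' @export
simulate_gene_sets <- function(cfg) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$rng_seed + 1L)
  genes <- .synth_genes(cfg)
  themes <- c("JAK STAT signaling", "MET signaling", "EPH Ephrin signaling",
              "TNF signaling", "Interleukin signaling", "WNT signaling",
              "NOTCH signaling", "MAPK cascade", "PI3K AKT signaling",
              "Integrin cell adhesion")
  sets <- vector("list", cfg$n_pathways)
  nms <- character(cfg$n_pathways)
  size_pool <- seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2])
  for (i in seq_len(cfg$n_pathways)) {
    size <- size_pool[sample.int(length(size_pool), 1)]
    sets[[i]] <- sample(genes, size)
    nms[i] <- if (i <= cfg$n_family_pathways) {
      sprintf("%s pathway %02d", cfg$family_keyword, i)
    } else {
      sprintf("%s pathway %02d", themes[((i - 1) %% length(themes)) + 1], i)
    }
  }
  names(sets) <- nms
  gene_set_db(sets, source = "synthetic")
}

#' Simulate cohort metadata and an expression matrix with planted signal
#'
#' Builds the sample table (two arms, two timepoints per patient,
#' responders assigned per arm fraction), draws per-gene baseline means
#' uniformly on the log2 scale, adds the configured planted mean shifts
#' to the group-1 samples of the named comparisons, optionally adds
#' per-gene batch shifts, and finally i.i.d. Gaussian noise.
#'
#' @param cfg a `SynthConfig`.
#' @param pathways the `GeneSetDB` the planted pathway indices refer to;
#'   defaults to [simulate_gene_sets()] under the same config.
#' @return list with `expr` (`ExpressionMatrix`, `log2_tpm1`), `meta`
#'   (`SampleTable`) and `truth` (a `GroundTruth` list: per planted
#'   effect the affected genes, samples and delta, plus response labels).
#' @export
simulate_cohort <- function(cfg, pathways = simulate_gene_sets(cfg)) {
  stopifnot(inherits(cfg, "SynthConfig"))
  meta <- .synth_meta(cfg)
  genes <- .synth_genes(cfg)
  set.seed(cfg$rng_seed + 2L)
  base_mean <- stats::runif(cfg$n_genes, cfg$baseline_mean_range[1],
                            cfg$baseline_mean_range[2])
  mu <- matrix(base_mean, cfg$n_genes, nrow(meta),
               dimnames = list(genes, meta$sample_id))
  cmps <- standard_comparisons(meta)
  planted <- list()
  for (pl in cfg$planted_pathways) {
    nm <- if (is.numeric(pl$pathway)) names(pathways$sets)[pl$pathway] else pl$pathway
    if (is.na(nm) || !nm %in% names(pathways$sets)) {
      stop("planted pathway not found: ", pl$pathway)
    }
    members <- pathways$sets[[nm]]
    if (pl$n_affected > length(members)) {
      stop("n_affected exceeds pathway size for ", nm)
    }
    if (!pl$comparison %in% names(cmps)) {
      stop("unknown planted comparison: ", pl$comparison)
    }
    affected <- members[seq_len(pl$n_affected)]
    target <- cmps[[pl$comparison]]$g1_samples
    mu[affected, target] <- mu[affected, target] + pl$delta
    planted[[length(planted) + 1L]] <- list(
      pathway = nm, comparison = pl$comparison,
      genes = affected, samples = target, delta = pl$delta
    )
  }
  if (!is.null(cfg$batch_effect)) {
    nb <- cfg$batch_effect$n_batches
    shift <- matrix(stats::rnorm(cfg$n_genes * nb, 0, cfg$batch_effect$shift_sd),
                    cfg$n_genes, nb)
    b_idx <- match(meta$batch, unique(meta$batch))
    mu <- mu + shift[, b_idx]
  }
  vals <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                      nrow(mu), ncol(mu))
  truth <- structure(list(
    planted = planted,
    response = stats::setNames(meta$response, meta$sample_id),
    planted_pathways = vapply(planted, `[[`, character(1), "pathway")
  ), class = "GroundTruth")
  list(expr = expression_matrix(vals, "log2_tpm1"), meta = meta,
       truth = truth)
}

.synth_meta <- function(cfg) {
  rows <- list()
  for (arm in c("TNFi", "IL17Ai")) {
    n <- cfg$n_patients_per_arm
    n_resp <- round(cfg$responder_fraction[[arm]] * n)
    for (i in seq_len(n)) {
      pid <- sprintf("%s_P%02d", arm, i)
      resp <- if (i <= n_resp) "responder" else "nonresponder"
      for (tp in c("baseline", "month3")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s", pid, if (tp == "baseline") "BL" else "M3"),
          patient_id = pid, arm = arm, timepoint = tp, response = resp,
          batch = "B1", stringsAsFactors = FALSE
        )
      }
    }
  }
  meta <- do.call(rbind, rows)
  if (!is.null(cfg$batch_effect)) {
    nb <- cfg$batch_effect$n_batches
    meta$batch <- sprintf("B%d", ((seq_len(nrow(meta)) - 1L) %% nb) + 1L)
  }
  sample_table(meta)
}

#' Simulate a pathway-modular PPI network
#'
#' Gene pairs sharing at least one pathway are connected with probability
#' `ppi_within_pathway_prob`; all other pairs with
#' `ppi_background_prob`. The result is a simple undirected graph over
#' all genes (isolated genes kept as nodes).
#'
#' @param cfg a `SynthConfig`.
#' @param pathways a `GeneSetDB` defining the modules.
#' @return an `igraph` network.
#' @export
simulate_network <- function(cfg, pathways = simulate_gene_sets(cfg)) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$rng_seed + 3L)
  genes <- .synth_genes(cfg)
  n <- length(genes)
  shared_keys <- character()
  for (s in pathways$sets) {
    idx <- sort(match(s, genes))
    if (length(idx) >= 2) {
      pr <- utils::combn(idx, 2)
      shared_keys <- c(shared_keys, paste(pr[1, ], pr[2, ]))
    }
  }
  shared_keys <- unique(shared_keys)
  within_keep <- shared_keys[stats::runif(length(shared_keys)) <
                               cfg$ppi_within_pathway_prob]
  n_all <- choose(n, 2)
  n_bg_pairs <- n_all - length(shared_keys)
  k_bg <- stats::rbinom(1, n_bg_pairs, cfg$ppi_background_prob)
  bg_keys <- character()
  while (length(bg_keys) < k_bg) {
    need <- k_bg - length(bg_keys)
    i <- sample.int(n, 2L * need, replace = TRUE)
    j <- sample.int(n, 2L * need, replace = TRUE)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    ok <- lo < hi
    keys <- paste(lo[ok], hi[ok])
    keys <- setdiff(unique(keys), c(shared_keys, bg_keys))
    bg_keys <- c(bg_keys, utils::head(keys, need))
  }
  keys <- c(within_keep, bg_keys)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    edges <- cbind(genes[as.integer(parts[, 1])], genes[as.integer(parts[, 2])])
  } else {
    edges <- matrix(character(), 0, 2)
  }
  ppi_network(edges, nodes = genes)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying the three generators together under one
#' config: pathway collection, cohort + expression, and PPI network.
#'
#' @param cfg a `SynthConfig`.
#' @return list: `gene_sets`, `expr`, `meta`, `truth`, `network`.
#' @export
simulate_study <- function(cfg) {
  gs <- simulate_gene_sets(cfg)
  cohort <- simulate_cohort(cfg, gs)
  net <- simulate_network(cfg, gs)
  list(gene_sets = gs, expr = cohort$expr, meta = cohort$meta,
       truth = cohort$truth, network = net)
}

#' Write all study files to a directory
#'
#' Emits `expression.tsv`, `metadata.tsv`, `ppi.tsv`, `pathways.gmt` and
#' `truth.tsv` (affected gene / comparison / delta rows).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(study$expr, file.path(dir, "expression.tsv"))
  write_sample_table(study$meta, file.path(dir, "metadata.tsv"))
  write_ppi(study$network, file.path(dir, "ppi.tsv"))
  write_gmt(study$gene_sets, file.path(dir, "pathways.gmt"))
  planted <- study$truth$planted
  rows <- if (length(planted)) {
    do.call(rbind, lapply(planted, function(pl) {
      data.frame(pathway = pl$pathway, comparison = pl$comparison,
                 gene = pl$genes, delta = pl$delta,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(pathway = character(), comparison = character(),
               gene = character(), delta = numeric())
  }
  utils::write.table(rows, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
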