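#' Hypergeometric test for the overlap of two gene lists
#'
#' Upper-tail probability of observing at least the realized overlap when
#' two lists of the given sizes are drawn without replacement from the
#' universe. The tail is accumulated from log hypergeometric densities
#' (log-sum-exp), so tiny p-values (< 1e-300 territory) remain accurate.
#'
#' @param list_a,list_b character vectors, both subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return an `OverlapResult` list: `N`, `K` (=|A|), `n` (=|B|), `k`
#'   (=|A ∩ B|), `p_hypergeom`.
#' @export
hypergeom_overlap <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  a <- unique(list_a)
  b <- unique(list_b)
  out_a <- setdiff(a, universe)
  out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b)) {
    stop("gene(s) outside the universe: ",
         paste(utils::head(c(out_a, out_b), 10), collapse = ", "))
  }
  N <- length(universe)
  K <- length(a)
  n <- length(b)
  k <- length(intersect(a, b))
  structure(list(N = N, K = K, n = n, k = k,
                 p_hypergeom = .hyper_upper_tail(k, K, n, N)),
            class = "OverlapResult")
}

# P(X >= k), X ~ Hypergeometric(N, K, n), via log-space summation
.hyper_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- seq.int(k, min(K, n))
  lp <- stats::dhyper(js, K, N - K, n, log = TRUE)
  mx <- max(lp)
  min(1, exp(mx + log(sum(exp(lp - mx)))))
}

#' Randomization (permutation) test for gene-list overlap
#'
#' Draws `B` pairs of uniform random subsets of the observed sizes from
#' the universe and compares their overlaps with the observed one. The
#' p-value uses the add-one convention `p = (1 + #{>= observed}) / (B + 1)`
#' and is therefore never smaller than `1 / (B + 1)`.
#'
#' @inheritParams hypergeom_overlap
#' @param B number of random replicates (>= 1).
#' @param seed integer seed; the result is reproducible given the seed.
#' @return an `OverlapResult` with `p_randomization` and `B` filled in
#'   addition to the [hypergeom_overlap()] fields.
#' @export
randomization_overlap <- function(list_a, list_b, universe, B = 1000,
                                  seed = NULL) {
  res <- hypergeom_overlap(list_a, list_b, universe)
  stopifnot(B >= 1)
  N <- res$N
  if (res$K > N || res$n > N) stop("list sizes exceed the universe")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  memb <- logical(N)
  for (i in seq_len(B)) {
    x <- sample.int(N, res$K)
    y <- sample.int(N, res$n)
    memb[] <- FALSE
    memb[x] <- TRUE
    if (sum(memb[y]) >= res$k) hits <- hits + 1L
  }
  res$p_randomization <- (1 + hits) / (B + 1)
  res$B <- as.integer(B)
  res
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("Overlap: k=%d of K=%d x n=%d in N=%d; hypergeometric p=%.3g",
              x$k, x$K, x$n, x$N, x$p_hypergeom))
  if (!is.null(x$p_randomization)) {
    cat(sprintf("; randomization p=%.3g (B=%d)", x$p_randomization, x$B))
  }
  cat("\n")
  invisible(x)
}

#' Expand a seed DEG list over a protein-interaction network
#'
#' Overlays fold changes on the PPI network and harvests interacting gene
#' pairs that both pass the (relaxed) fold-change gate. In
#' `seed_anchored` mode a qualifying edge must additionally touch a seed
#' gene (one-hop expansion around the seeds); in `pairwise` mode any
#' qualifying interacting pair contributes. Seeds always remain in the
#' expanded list, including seeds absent from the network. Genes missing
#' from the DGE table never qualify.
#'
#' @param seeds character vector of seed genes.
#' @param tbl a `DGETable` supplying `fc_signed` and `p`.
#' @param net an `igraph` PPI network.
#' @param fc_threshold linear fold-change gate (>= 1) applied to both
#'   endpoints of an edge.
#' @param mode `"seed_anchored"` or `"pairwise"`.
#' @return an `ExpansionResult` list: `seeds`, `qualifying_edges`
#'   (two-column matrix), `expanded` (ordered by ascending p then symbol),
#'   `mode`, `fc_threshold`.
#' @export
expand_by_ppi <- function(seeds, tbl, net, fc_threshold = 1.2,
                          mode = c("seed_anchored", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(fc_threshold >= 1)
  seeds <- unique(as.character(seeds))
  absfc <- setNames(abs(tbl$fc_signed), tbl$gene)
  el <- igraph::as_edgelist(net)
  if (nrow(el)) {
    pass <- function(g) !is.na(absfc[g]) & absfc[g] >= fc_threshold
    qual <- pass(el[, 1]) & pass(el[, 2])
    if (mode == "seed_anchored") {
      qual <- qual & (el[, 1] %in% seeds | el[, 2] %in% seeds)
    }
    qedges <- el[qual, , drop = FALSE]
  } else {
    qedges <- matrix(character(), 0, 2)
  }
  expanded <- union(seeds, as.vector(qedges))
  p <- setNames(tbl$p, tbl$gene)[expanded]
  expanded <- expanded[order(p, expanded, na.last = TRUE)]
  structure(list(seeds = seeds, qualifying_edges = qedges,
                 expanded = expanded, mode = mode,
                 fc_threshold = fc_threshold),
            class = "ExpansionResult")
}

#' @export
print.ExpansionResult <- function(x, ...) {
  cat(sprintf(
    "PPI expansion (%s, |FC| >= %g): %d seed(s) -> %d gene(s) via %d edge(s)\n",
    x$mode, x$fc_threshold, length(x$seeds), length(x$expanded),
    nrow(x$qualifying_edges)
  ))
  invisible(x)
}

#' Write an expansion result as node and edge tables
#'
#' Emits `<prefix>_nodes.tsv` (gene, fc_signed, p, seed flag, qualifying
#' degree) and `<prefix>_edges.tsv`, suitable for import into generic
#' graph viewers.
#'
#' @param x an `ExpansionResult`.
#' @param tbl the `DGETable` used for the expansion.
#' @param prefix output path prefix.
#' @export
write_expansion <- function(x, tbl, prefix) {
  idx <- match(x$expanded, tbl$gene)
  deg <- table(factor(as.vector(x$qualifying_edges), levels = x$expanded))
  nodes <- data.frame(
    gene = x$expanded,
    fc_signed = tbl$fc_signed[idx],
    p = tbl$p[idx],
    seed = as.integer(x$expanded %in% x$seeds),
    qualifying_degree = as.integer(deg),
    stringsAsFactors = FALSE
  )
  utils::write.table(nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  edges <- as.data.frame(x$qualifying_edges, stringsAsFactors = FALSE)
  names(edges) <- c("symbol1", "symbol2")
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
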