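#' Hypergeometric pathway enrichment with BH-FDR
#'
#' For each pathway, tests whether the query list overlaps it more than
#' expected from uniform draws out of the universe. Pathway membership and
#' overlap counts are computed after intersecting with the universe;
#' pathways with no member in the universe are skipped with a message.
#' Benjamini-Hochberg adjusted q-values are computed across all tested
#' pathways; "enriched" means `q <= alpha`.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param db a `GeneSetDB`.
#' @param universe gene universe; defaults to the database universe. In a
#'   full analysis pass the measured genes (expression-matrix rows
#'   intersected with the database universe).
#' @param alpha BH significance level for the `enriched` flag.
#' @return data.frame of class `EnrichmentTable`: `pathway`, `k`, `K`,
#'   `n`, `N`, `p`, `q`, `enriched`, sorted by ascending p (ties by name).
#' @export
enrich <- function(query, db, universe = db$universe, alpha = 0.05) {
  stopifnot(inherits(db, "GeneSetDB"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("query gene list is empty")
  universe <- unique(as.character(universe))
  out <- setdiff(query, universe)
  if (length(out)) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(out, 10), collapse = ", "))
  }
  if (length(db$sets) == 0L) stop("gene-set database is empty")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(db$sets), function(nm) {
    P <- intersect(db$sets[[nm]], universe)
    K <- length(P)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, P))
    data.frame(pathway = nm, k = k, K = K, n = n, N = N,
               p = .hyper_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) {
    message(skipped, " pathway(s) with no member in the universe skipped")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no pathway has members in the universe")
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q <= alpha
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentTable", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as an explicit
#' pipeline surface so the correction applied to enrichment p-values is
#' visible and swappable.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, clipped to 1, in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Default stopword list for pathway-title tokenization
#'
#' @return lowercase character vector.
#' @export
default_stopwords <- function() {
  c("a", "an", "and", "as", "at", "by", "for", "from", "in", "into",
    "of", "on", "or", "the", "their", "through", "to", "via", "with")
}

#' Key-term weights over enriched pathway titles
#'
#' The word-cloud statistic: titles of enriched pathways (`q <= alpha`)
#' are tokenized (lowercase, split on non-alphanumeric characters;
#' stopwords, single characters and pure numbers dropped; no stemming, so
#' "gtpase" and "gtpases" stay distinct) and each token is weighted by the
#' best (smallest) enrichment p among the pathways whose title contains
#' it, on the `-log10` scale.
#'
#' @param rows an `EnrichmentTable`.
#' @param alpha q-value threshold defining "enriched".
#' @param stopwords tokens to drop.
#' @return data.frame `token`, `weight`, `support` (number of contributing
#'   pathways), sorted by descending weight, ties lexicographic. Empty
#'   when no pathway is enriched.
#' @export
key_terms <- function(rows, alpha = 0.05, stopwords = default_stopwords()) {
  enr <- rows[rows$q <= alpha, , drop = FALSE]
  empty <- data.frame(token = character(), weight = numeric(),
                      support = integer(), stringsAsFactors = FALSE)
  if (nrow(enr) == 0L) return(empty)
  tok_list <- lapply(enr$pathway, .tokenize_title, stopwords = stopwords)
  recs <- data.frame(
    token = unlist(tok_list),
    p = rep(enr$p, lengths(tok_list)),
    stringsAsFactors = FALSE
  )
  if (nrow(recs) == 0L) return(empty)
  agg <- do.call(rbind, lapply(split(recs$p, recs$token), function(ps) {
    data.frame(weight = -log10(max(min(ps), .Machine$double.xmin)),
               support = length(ps))
  }))
  out <- data.frame(token = rownames(agg), weight = agg$weight,
                    support = agg$support, stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$token), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.tokenize_title <- function(title, stopwords) {
  toks <- strsplit(tolower(title), "[^a-z0-9]+")[[1]]
  toks <- unique(toks[nzchar(toks)])
  toks <- toks[nchar(toks) > 1L]
  toks <- toks[!grepl("^[0-9]+$", toks)]
  setdiff(toks, stopwords)
}

#' Tokens specific to one of two enrichment results
#'
#' Compares the key-term token sets of two analyses and returns the tokens
#' present among A's enriched-pathway titles but absent from B's, and vice
#' versa — the "which themes are specific to this arm" view.
#'
#' @param rows_a,rows_b `EnrichmentTable`s.
#' @param alpha q-value threshold defining "enriched".
#' @param stopwords tokens to drop.
#' @return list with `a_specific` and `b_specific` character vectors.
#' @export
differential_terms <- function(rows_a, rows_b, alpha = 0.05,
                               stopwords = default_stopwords()) {
  ta <- key_terms(rows_a, alpha, stopwords)$token
  tb <- key_terms(rows_b, alpha, stopwords)$token
  list(a_specific = sort(setdiff(ta, tb)),
       b_specific = sort(setdiff(tb, ta)))
}
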