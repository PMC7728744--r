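#' Build an undirected protein-protein interaction network
#'
#' Networks are stored as [igraph] graphs over gene symbols. Self-loops and
#' duplicate (A,B)/(B,A) pairs are removed so the result is always a simple
#' undirected graph.
#'
#' @param edges two-column character matrix (or data.frame) of gene-symbol
#'   pairs.
#' @param nodes optional extra node symbols (isolated nodes are kept).
#' @return an `igraph` object.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  n_self <- if (length(edges)) sum(edges[, 1] == edges[, 2]) else 0L
  if (n_self > 0) {
    message(n_self, " self-loop(s) dropped")
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  all_nodes <- sort(unique(c(as.vector(edges), as.character(nodes))))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = all_nodes
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' @rdname ppi_network
#' @param net an `igraph` network.
#' @export
ppi_nodes <- function(net) sort(igraph::V(net)$name)

#' @rdname ppi_network
#' @export
ppi_edges <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) {
    return(matrix(character(), 0, 2, dimnames = list(NULL, c("symbol1", "symbol2"))))
  }
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  colnames(el) <- c("symbol1", "symbol2")
  el
}

#' Read a PPI edge list from a delimited file
#'
#' Consumes IID-style exports: a TSV with (at least) two symbol columns;
#' any additional annotation columns are ignored.
#'
#' @param path TSV file.
#' @param col_a,col_b names of the two interactor columns.
#' @return an `igraph` network (simple, undirected).
#' @export
read_ppi <- function(path, col_a = "symbol1", col_b = "symbol2") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(c(col_a, col_b), names(df))
  if (length(miss)) {
    stop(sprintf("column(s) %s not found; available: %s",
                 paste(miss, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  }
  ppi_network(cbind(df[[col_a]], df[[col_b]]))
}

#' @rdname read_ppi
#' @param net an `igraph` network.
#' @export
write_ppi <- function(net, path) {
  utils::write.table(as.data.frame(ppi_edges(net)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
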