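#' Construct a gene-set (pathway) database
#'
#' A named collection of pathway membership sets together with the gene
#' universe used for enrichment. Unless overridden the universe is the
#' union of all member symbols.
#'
#' @param sets named list of character vectors (pathway -> member symbols).
#' @param source free-text provenance label.
#' @param universe optional explicit universe; must contain every member.
#' @return a `GeneSetDB` (list with `sets`, `source`, `universe`).
#' @export
gene_set_db <- function(sets, source = "", universe = NULL) {
  if (length(sets) == 0L) {
    return(structure(list(sets = setNames(list(), character()),
                          source = source, universe = character()),
                     class = "GeneSetDB"))
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every gene set needs a pathway name")
  }
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) stop("duplicate pathway name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) are not allowed")
  members <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- sort(unique(as.character(universe)))
    out <- setdiff(members, universe)
    if (length(out)) {
      stop("member symbol(s) outside universe: ", paste(utils::head(out, 5), collapse = ", "))
    }
  }
  structure(list(sets = sets, source = source, universe = universe),
            class = "GeneSetDB")
}

#' @export
print.GeneSetDB <- function(x, ...) {
  cat(sprintf("GeneSetDB: %d sets, %d universe genes%s\n",
              length(x$sets), length(x$universe),
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate member
#' symbols within a line are stored once.
#'
#' @param path GMT file.
#' @param source provenance label (defaults to the file name).
#' @return a `GeneSetDB`.
#' @export
read_gmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >= 1 member",
                   i, length(fields)))
    }
    sets[[fields[1]]] <- fields[-(1:2)]
  }
  gene_set_db(sets, source = source)
}

#' @rdname read_gmt
#' @param db a `GeneSetDB`.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, db$source, db$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# case-insensitive comparison ignoring '-', '_' and whitespace
.normalize_term <- function(x) gsub("[-_[:space:]]+", "", tolower(x))

#' Retrieve pathways whose name matches a keyword
#'
#' Matching is case-insensitive and ignores hyphen/underscore/whitespace
#' differences, so "rho-gtpase" finds both "RHO GTPase cycle" and
#' "Signaling by Rho-GTPases". An empty result is returned (not an error)
#' when nothing matches.
#'
#' @param db a `GeneSetDB`.
#' @param keyword non-empty search string.
#' @return a `GeneSetDB` restricted to the matching pathways; the universe
#'   is inherited from `db`.
#' @export
retrieve_sets_by_keyword <- function(db, keyword) {
  stopifnot(inherits(db, "GeneSetDB"))
  if (!nzchar(keyword)) stop("keyword must be non-empty")
  hit <- grepl(.normalize_term(keyword), .normalize_term(names(db$sets)),
               fixed = TRUE)
  if (!any(hit)) {
    message("no pathway name matches keyword '", keyword, "'")
    return(structure(list(sets = setNames(list(), character()),
                          source = db$source, universe = db$universe),
                     class = "GeneSetDB"))
  }
  gene_set_db(db$sets[hit], source = db$source, universe = db$universe)
}
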