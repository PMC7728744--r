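#' Define a two-group comparison over the sample table
#'
#' A comparison is a pair of filters over `SampleTable` columns. Filters
#' are named lists of allowed values, e.g.
#' `list(arm = "TNFi", response = "responder", timepoint = "baseline")`.
#' Call [resolve_comparison()] (or [standard_comparisons()], which does it
#' for you) to bind the filters to concrete sample ids.
#'
#' @param name comparison label; by convention `group1_vs_group2`.
#' @param group1,group2 named lists of allowed values per metadata column.
#' @param paired whether samples pair one-to-one by `patient_id` (used for
#'   pre/post comparisons).
#' @return a `ComparisonSpec`.
#' @export
comparison_spec <- function(name, group1, group2, paired = FALSE) {
  stopifnot(is.character(name), nzchar(name), is.list(group1), is.list(group2))
  structure(list(name = name, group1 = group1, group2 = group2,
                 paired = isTRUE(paired),
                 g1_samples = NULL, g2_samples = NULL),
            class = "ComparisonSpec")
}

#' @rdname comparison_spec
#' @param meta a `SampleTable`.
#' @param filter a named list of allowed values.
#' @return `select_samples`: the matching sample ids.
#' @export
select_samples <- function(meta, filter) {
  bad <- setdiff(names(filter), names(meta))
  if (length(bad)) {
    stop("filter references unknown column(s): ", paste(bad, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(meta))
  for (col in names(filter)) {
    keep <- keep & meta[[col]] %in% filter[[col]]
  }
  meta$sample_id[keep]
}

#' Bind a comparison's filters to concrete samples
#'
#' Validates that the two groups are non-empty and disjoint and, for paired
#' comparisons, that samples pair one-to-one by patient.
#'
#' @param cmp a `ComparisonSpec`.
#' @param meta a `SampleTable`.
#' @return the `ComparisonSpec` with `g1_samples` / `g2_samples` filled.
#' @export
resolve_comparison <- function(cmp, meta) {
  stopifnot(inherits(cmp, "ComparisonSpec"))
  g1 <- select_samples(meta, cmp$group1)
  g2 <- select_samples(meta, cmp$group2)
  if (length(g1) == 0L) {
    stop("comparison '", cmp$name, "': group1 filter selects no samples")
  }
  if (length(g2) == 0L) {
    stop("comparison '", cmp$name, "': group2 filter selects no samples")
  }
  if (length(intersect(g1, g2))) {
    stop("comparison '", cmp$name, "': groups overlap")
  }
  if (cmp$paired) {
    p1 <- meta$patient_id[match(g1, meta$sample_id)]
    p2 <- meta$patient_id[match(g2, meta$sample_id)]
    if (anyDuplicated(p1) || anyDuplicated(p2) ||
        length(g1) != length(g2) || !setequal(p1, p2)) {
      stop("comparison '", cmp$name,
           "': paired groups must match one-to-one by patient_id")
    }
    ord <- order(p1)
    g1 <- g1[ord]
    g2 <- g2[match(p1[ord], p2)]
  }
  cmp$g1_samples <- g1
  cmp$g2_samples <- g2
  cmp
}

#' The seven preset responder-group comparisons
#'
#' The comparisons the workflow profiles in detail: responder vs
#' non-responder within each arm at baseline, responder-responder and
#' non-responder-non-responder across arms at baseline, and baseline vs
#' month-3 within TNFi responders, IL-17Ai responders and TNFi
#' non-responders.
#'
#' @param meta a `SampleTable` covering both arms, both responses and both
#'   timepoints.
#' @param paired_prepost whether the baseline-vs-month3 comparisons pair by
#'   patient (default unpaired).
#' @return a named list of 7 resolved `ComparisonSpec`s.
#' @export
standard_comparisons <- function(meta, paired_prepost = FALSE) {
  grp <- function(arm, response, timepoint) {
    list(arm = arm, response = response, timepoint = timepoint)
  }
  specs <- list(
    comparison_spec("TNFi_R_vs_NR_baseline",
                    grp("TNFi", "responder", "baseline"),
                    grp("TNFi", "nonresponder", "baseline")),
    comparison_spec("IL17Ai_R_vs_NR_baseline",
                    grp("IL17Ai", "responder", "baseline"),
                    grp("IL17Ai", "nonresponder", "baseline")),
    comparison_spec("TNFi_R_vs_IL17Ai_R_baseline",
                    grp("TNFi", "responder", "baseline"),
                    grp("IL17Ai", "responder", "baseline")),
    comparison_spec("TNFi_NR_vs_IL17Ai_NR_baseline",
                    grp("TNFi", "nonresponder", "baseline"),
                    grp("IL17Ai", "nonresponder", "baseline")),
    comparison_spec("TNFi_R_baseline_vs_month3",
                    grp("TNFi", "responder", "baseline"),
                    grp("TNFi", "responder", "month3"),
                    paired = paired_prepost),
    comparison_spec("IL17Ai_R_baseline_vs_month3",
                    grp("IL17Ai", "responder", "baseline"),
                    grp("IL17Ai", "responder", "month3"),
                    paired = paired_prepost),
    comparison_spec("TNFi_NR_baseline_vs_month3",
                    grp("TNFi", "nonresponder", "baseline"),
                    grp("TNFi", "nonresponder", "month3"),
                    paired = paired_prepost)
  )
  specs <- lapply(specs, resolve_comparison, meta = meta)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
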