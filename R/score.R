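#' Cox screening of sub-pathways across cohorts
#'
#' Recomputes the PAS of each candidate sub-pathway within every cohort,
#' fits the univariate Cox model per cohort, applies a within-cohort
#' multiplicity correction (Bonferroni by default) and calls a sub-pathway
#' significant in a cohort when its adjusted p-value is below `alpha`. A
#' sub-pathway is *selected* when it is significant in every supplied
#' cohort; if more than `max_selected` survive, the `max_selected` with the
#' best combined rank of adjusted p-values (via [combine_ranks()]) are
#' kept. Sub-pathways whose genes are not measured in every cohort are
#' dropped from testing with a message.
#'
#' @param subpaths A `subpathway_set` from [decompose_crosstalk()].
#' @param cohorts List of [new_cohort()] objects (at least one).
#' @param alpha Significance threshold on the adjusted p-value.
#' @param correction Multiplicity correction: `"bonferroni"` (default) or
#'   `"BH"` (Benjamini-Hochberg).
#' @param max_selected Cap on the number of selected sub-pathways.
#' @return A `subpathway_scores` object: list with `scores` (long tibble:
#'   `subpathway_id`, `cohort_id`, `coef`, `p`, `p_adj`, `significant`),
#'   `selected` (character vector of selected ids, best combined rank
#'   first), plus the call parameters. [tidy()] returns the long tibble,
#'   [glance()] a one-row summary.
#' @export
score_subpathways <- function(subpaths, cohorts, alpha = 0.01,
                              correction = c("bonferroni", "BH"),
                              max_selected = 100) {
  correction <- arg_match(correction)
  stopifnot(inherits(subpaths, "subpathway_set"))
  if (!is.list(cohorts) || length(cohorts) == 0 ||
      !all(map_lgl(cohorts, inherits, "cohort"))) {
    abort("Supply a non-empty list of cohort objects.",
          class = "pascrosstalk_input_error")
  }
  if (nrow(subpaths) == 0) {
    abort("No sub-pathways to score.", class = "pascrosstalk_input_error")
  }

  pas_list <- map(cohorts, function(co) {
    withCallingHandlers(
      subpathway_pas(co, subpaths),
      message = function(m) invokeRestart("muffleMessage"))
  })
  testable <- purrr::reduce(map(pas_list, rownames), intersect)
  n_dropped <- nrow(subpaths) - length(testable)
  if (n_dropped > 0) {
    inform(sprintf(
      "%d sub-pathway(s) not measurable in every cohort were dropped from testing.",
      n_dropped))
  }
  if (length(testable) == 0) {
    abort("No sub-pathway is measurable in every cohort.",
          class = "pascrosstalk_empty_result")
  }

  scores <- map2(pas_list, cohorts, function(pas, co) {
    surv <- co$survival[match(colnames(pas), co$survival$sample_id), ]
    rows <- map(testable, function(id) {
      row <- unclass(pas)[id, ]
      coef <- NA_real_
      p <- withCallingHandlers(
        pathway_survival_pvalue(row, surv),
        warning = function(w) {
          if (inherits(w, "pascrosstalk_uninformative")) {
            invokeRestart("muffleWarning")
          }
        })
      if (sd(row) > 0 && sum(surv$event) > 0) {
        fit <- tryCatch(
          survival::coxph(survival::Surv(surv$time, surv$event) ~ row),
          error = function(e) NULL)
        if (!is.null(fit)) coef <- unname(stats::coef(fit))
      }
      tibble(subpathway_id = id, cohort_id = co$cohort_id,
             coef = coef, p = p)
    })
    bind_rows(rows) |>
      mutate(p_adj = p.adjust(.data$p, method = correction),
             significant = .data$p_adj < alpha)
  }) |>
    bind_rows()

  sel <- scores |>
    group_by(.data$subpathway_id) |>
    summarise(all_sig = all(.data$significant), .groups = "drop") |>
    filter(.data$all_sig) |>
    pull("subpathway_id")

  if (length(sel) > 0) {
    ranking <- combine_ranks(
      scores |>
        filter(.data$subpathway_id %in% sel) |>
        select(pathway_id = "subpathway_id", "cohort_id", p = "p_adj"))
    sel <- ranking$pathway_id[ranking$combined_rank <=
                                min(max_selected, nrow(ranking))]
  }

  structure(
    list(scores = scores, selected = sel, alpha = alpha,
         correction = correction, max_selected = max_selected,
         n_tested = length(testable), n_dropped = n_dropped),
    class = "subpathway_scores")
}

#' @export
print.subpathway_scores <- function(x, ...) {
  cat(sprintf(
    "<subpathway_scores: %d tested across %d cohort(s), %d selected (%s, alpha = %g)>\n",
    x$n_tested, length(unique(x$scores$cohort_id)), length(x$selected),
    x$correction, x$alpha))
  invisible(x)
}

#' @rdname score_subpathways
#' @param x A `subpathway_scores` object.
#' @param ... Ignored.
#' @export
tidy.subpathway_scores <- function(x, ...) {
  mutate(x$scores, selected = .data$subpathway_id %in% x$selected)
}

#' @rdname score_subpathways
#' @export
glance.subpathway_scores <- function(x, ...) {
  tibble(n_tested = x$n_tested, n_dropped = x$n_dropped,
         n_cohorts = length(unique(x$scores$cohort_id)),
         n_selected = length(x$selected),
         alpha = x$alpha, correction = x$correction)
}
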