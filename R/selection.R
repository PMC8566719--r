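#' Survival association p-value of one activity score
#'
#' Fits a univariate Cox proportional-hazards regression of survival on
#' the continuous activity score and returns the score-test p-value — the
#' log-rank generalization for a continuous covariate. Uninformative rows
#' (constant score, or no observed event) return the sentinel p = 1 with a
#' warning rather than failing, so whole-collection screens never abort on
#' a degenerate pathway.
#'
#' @param pas_row Numeric vector of activity scores, one per sample, in
#'   the same order as `survival`.
#' @param survival Data frame with columns `time` and `event`.
#' @return A p-value in `(0, 1]`.
#' @export
pathway_survival_pvalue <- function(pas_row, survival) {
  if (length(pas_row) != nrow(survival)) {
    abort("pas_row and survival must cover the same samples.",
          class = "pascrosstalk_input_error")
  }
  if (sum(survival$event) == 0 || sd(pas_row) == 0) {
    warn("Uninformative score (constant PAS or no events); returning p = 1.",
         class = "pascrosstalk_uninformative")
    return(1)
  }
  p <- tryCatch({
    fit <- survival::coxph(
      survival::Surv(survival$time, survival$event) ~ pas_row)
    unname(summary(fit)$sctest["pvalue"])
  }, error = function(e) NA_real_)
  if (is.na(p)) {
    warn("Cox fit failed; returning p = 1.",
         class = "pascrosstalk_uninformative")
    return(1)
  }
  max(p, .Machine$double.xmin)
}

#' Per-pathway survival p-values for one cohort
#'
#' @param pas A `pas_matrix` for one cohort.
#' @param survival The cohort's survival tibble (or a [new_cohort()], from
#'   which survival is taken); samples must match the PAS columns.
#' @return Tibble with columns `pathway_id`, `cohort_id`, `p`.
#' @export
cohort_survival_pvalues <- function(pas, survival) {
  if (inherits(survival, "cohort")) survival <- survival$survival
  survival <- as_tibble(survival)
  if (!setequal(survival$sample_id, colnames(pas))) {
    abort("PAS columns and survival samples do not match.",
          class = "pascrosstalk_input_error")
  }
  survival <- survival[match(colnames(pas), survival$sample_id), ]
  p <- apply(unclass(pas), 1, pathway_survival_pvalue, survival = survival)
  tibble(pathway_id = rownames(pas),
         cohort_id = attr(pas, "cohort_id"),
         p = unname(p))
}

#' Aggregate per-cohort survival ranks (sure independence screening)
#'
#' Within each cohort, pathways are ranked ascending by p-value (rank 1 =
#' most significant, ties broken by pathway id so ranks are always a
#' permutation of 1..m). The combined order is by the sum of per-cohort
#' ranks — the marginal-utility aggregation of sure independence screening
#' applied across cohorts — with ties broken by the minimum single-cohort
#' p-value and then pathway id, so the combined ranking is total and
#' invariant to input order and to any strictly monotone transform of the
#' p-values.
#'
#' @param per_cohort_pvalues Either a long tibble with columns
#'   `pathway_id`, `cohort_id`, `p` (e.g. row-bound output of
#'   [cohort_survival_pvalues()]), or a numeric matrix pathways x cohorts
#'   with dimnames.
#' @return A `pathway_ranking` tibble: `pathway_id`, one `rank_<cohort>`
#'   column per cohort, `rank_sum`, `min_p`, `combined_rank`, sorted by
#'   `combined_rank`.
#' @export
combine_ranks <- function(per_cohort_pvalues) {
  if (is.matrix(per_cohort_pvalues)) {
    m <- per_cohort_pvalues
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      abort("p-value matrix needs pathway rownames and cohort colnames.",
            class = "pascrosstalk_input_error")
    }
    long <- tibble(pathway_id = rep(rownames(m), times = ncol(m)),
                   cohort_id = rep(colnames(m), each = nrow(m)),
                   p = as.vector(m))
  } else {
    long <- as_tibble(per_cohort_pvalues)
    if (!all(c("pathway_id", "cohort_id", "p") %in% names(long))) {
      abort("Need columns pathway_id, cohort_id, p.",
            class = "pascrosstalk_input_error")
    }
  }
  if (any(is.na(long$p))) {
    abort("Missing p-values are not allowed.",
          class = "pascrosstalk_input_error")
  }
  counts <- count(long, .data$pathway_id)
  n_cohorts <- length(unique(long$cohort_id))
  if (any(counts$n != n_cohorts)) {
    abort("Every pathway must be scored in every cohort.",
          class = "pascrosstalk_input_error")
  }
  ranked <- long |>
    group_by(.data$cohort_id) |>
    mutate(rank = order(order(.data$p, .data$pathway_id))) |>
    ungroup()
  wide <- ranked |>
    select("pathway_id", "cohort_id", "rank") |>
    tidyr::pivot_wider(names_from = "cohort_id", values_from = "rank",
                       names_prefix = "rank_")
  summ <- ranked |>
    group_by(.data$pathway_id) |>
    summarise(rank_sum = sum(.data$rank), min_p = min(.data$p),
              .groups = "drop")
  out <- left_join(wide, summ, by = "pathway_id") |>
    arrange(.data$rank_sum, .data$min_p, .data$pathway_id) |>
    mutate(combined_rank = row_number())
  class(out) <- c("pathway_ranking", class(out))
  out
}

#' Select the top-n pathways from a combined ranking
#'
#' Returns exactly the `n` best pathways by combined rank. The default
#' n = 100 follows the screening convention of keeping a candidate count
#' well above N/log(N) for cohorts of a few hundred samples; a warning is
#' emitted if `cohort_sizes` are supplied and n falls below that bound for
#' any of them.
#'
#' @param ranking A `pathway_ranking` from [combine_ranks()].
#' @param collection The [gene_set_collection()] the ranking refers to.
#' @param n Number of pathways to keep.
#' @param cohort_sizes Optional integer vector of per-cohort sample sizes
#'   used for the N/log(N) sanity warning.
#' @return A [gene_set_collection()] of the selected pathways, ordered by
#'   combined rank.
#' @export
select_top <- function(ranking, collection, n = 100, cohort_sizes = NULL) {
  stopifnot(inherits(ranking, "pathway_ranking"))
  collection <- as_gene_set_collection(collection)
  if (n > nrow(ranking)) {
    abort(sprintf("Requested top %d but only %d pathways are ranked.",
                  n, nrow(ranking)),
          class = "pascrosstalk_input_error")
  }
  if (!is.null(cohort_sizes)) {
    bound <- max(cohort_sizes / log(cohort_sizes))
    if (n < bound) {
      warn(sprintf(
        "n = %d is below the screening bound N/log(N) = %.1f for the largest cohort.",
        n, bound))
    }
  }
  keep <- ranking$pathway_id[ranking$combined_rank <= n]
  missing_ids <- setdiff(keep, collection$pathway_id)
  if (length(missing_ids) > 0) {
    abort("Ranking refers to pathways absent from the collection.",
          class = "pascrosstalk_input_error")
  }
  out <- collection[match(keep, collection$pathway_id), ]
  class(out) <- c("gene_set_collection", setdiff(class(out),
                                                 "gene_set_collection"))
  out
}
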