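#' Run the full pathway-crosstalk risk pipeline
#'
#' Chains every stage on a set of training cohorts and one held-out test
#' cohort: per-cohort PAS and Cox p-values for every pathway, combined
#' rank aggregation across cohorts, top-n selection, crosstalk
#' decomposition into sub-pathways, Bonferroni-screened Cox selection of
#' sub-pathways across all training cohorts, k = 2 clustering of the first
#' training cohort into G1/G2, classifier training on its sub-pathway PAS,
#' transfer of the subtype calls to the held-out cohort (PAS recomputed
#' there), and survival evaluation of the transferred labels with the
#' training Cox model as risk reference.
#'
#' @param train_cohorts List of [new_cohort()] objects; the first one is
#'   the clustering/training cohort.
#' @param test_cohort A held-out [new_cohort()].
#' @param collection The [gene_set_collection()] of candidate pathways.
#' @param n_top Pathways kept after rank aggregation (capped at the number
#'   available).
#' @param min_overlap,min_size Crosstalk decomposition thresholds.
#' @param alpha Adjusted-p threshold for sub-pathway selection.
#' @param correction Multiplicity correction for [score_subpathways()].
#' @param classifier Classifier kind for [train_classifier()].
#' @param seed Integer seed driving clustering, folds and splits.
#' @return List with `ranking`, `selected_pathways`, `subpaths`, `scores`,
#'   `features` (sub-pathway set used as features), `labels_train`,
#'   `model`, `labels_test`, `report_train`, `report_test`.
#' @export
run_crosstalk_pipeline <- function(train_cohorts, test_cohort, collection,
                                   n_top = 100, min_overlap = 3,
                                   min_size = 3, alpha = 0.01,
                                   correction = "bonferroni",
                                   classifier = "svm", seed = 1) {
  stopifnot(length(train_cohorts) >= 1)
  pvals <- map(train_cohorts, function(co) {
    pas <- compute_pas(co, collection)
    suppressWarnings(cohort_survival_pvalues(pas, co))
  }) |>
    bind_rows()
  ranking <- combine_ranks(pvals)
  n_top <- min(n_top, nrow(ranking))
  selected_pathways <- select_top(
    ranking, collection, n = n_top,
    cohort_sizes = map_int(train_cohorts,
                           function(co) nrow(co$survival)))
  subpaths <- decompose_crosstalk(selected_pathways,
                                  min_overlap = min_overlap,
                                  min_size = min_size)
  if (nrow(subpaths) == 0) {
    abort("No crosstalking pathway pair produced sub-pathways.",
          class = "pascrosstalk_empty_result")
  }
  scores <- score_subpathways(subpaths, train_cohorts, alpha = alpha,
                              correction = correction)
  if (length(scores$selected) == 0) {
    abort("No sub-pathway passed the cross-cohort significance screen.",
          class = "pascrosstalk_empty_result")
  }
  features_def <- subpathways_by_id(subpaths, scores$selected)

  anchor <- train_cohorts[[1]]
  features_train <- subpathway_pas(anchor, features_def)
  labels_train <- cluster_samples(features_train, anchor, k = 2,
                                  seed = seed + 1L)
  model <- train_classifier(features_train, labels_train,
                            kind = classifier, seed = seed + 2L)
  reference <- fit_risk_reference(labels_train, anchor)
  report_train <- evaluate(labels_train, anchor)

  features_test <- subpathway_pas(test_cohort, features_def)
  labels_test <- predict_groups(model, features_test)
  report_test <- evaluate(labels_test, test_cohort,
                          train_reference = reference)

  list(ranking = ranking, selected_pathways = selected_pathways,
       subpaths = subpaths, scores = scores, features = features_def,
       labels_train = labels_train, model = model,
       labels_test = labels_test, report_train = report_train,
       report_test = report_test)
}
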