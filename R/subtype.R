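km_group_summary <- function(labels_df, survival) {
  df <- left_join(labels_df, survival, by = "sample_id")
  if (any(is.na(df$time))) {
    abort("Every labelled sample needs a survival record.",
          class = "pascrosstalk_input_error")
  }
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = df)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list(
    paste0("group=", df$group[1]), names(tab)))
  tibble(group = sub("^group=", "", rownames(tab)),
         n = unname(tab[, "records"]),
         median_survival = unname(tab[, "median"]),
         rmean = unname(tab[, "rmean"]))
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k)[-1]) {
    if (sum(d2) <= 0) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

seeded_kmeans <- function(x, k, seed, restarts = 50) {
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(x, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = centers, iter.max = 100)),
        error = function(e) NULL)
      if (is.null(fit) || length(unique(fit$cluster)) < k) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) {
    abort("k-means failed to produce k non-empty clusters in 50 restarts.",
          class = "pascrosstalk_cluster_error")
  }
  best
}

#' Cluster samples into outcome-anchored risk groups
#'
#' Runs k-means (k-means++ initialization, 50 seeded restarts, best
#' within-cluster sum of squares kept) on the samples-by-features view of
#' a PAS matrix, then renames clusters by outcome so that the naming is
#' reproducible regardless of arbitrary cluster indices: groups are
#' ordered by Kaplan-Meier median survival (restricted mean as tie-break /
#' fallback when a median is not reached) and labelled `G1` (best outcome)
#' through `Gk`; with the default k = 2, `G2` is always the
#' aggressive, worse-survival group. Features are used unscaled: PAS is
#' already bounded in `[-1, 1]` on a common scale.
#'
#' @param features A `pas_matrix` (gene sets x samples); no missing values.
#' @param survival The cohort's survival tibble (or a [new_cohort()]) used
#'   only to anchor group names to outcome.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed making the restarts deterministic.
#' @return A `subtype_labels` tibble with columns `sample_id`, `group`
#'   (factor G1..Gk) and attributes `k`, `seed`, `feature_ids` and
#'   `group_summary` (per-group n, KM median, restricted mean).
#' @export
cluster_samples <- function(features, survival, k = 2, seed = 1) {
  stopifnot(inherits(features, "pas_matrix"))
  if (inherits(survival, "cohort")) survival <- survival$survival
  if (k < 2) {
    abort("k must be at least 2.", class = "pascrosstalk_input_error")
  }
  x <- t(unclass(features))
  if (nrow(x) < 2 * k) {
    abort("Need at least 2k samples to cluster.",
          class = "pascrosstalk_input_error")
  }
  if (anyNA(x)) {
    abort("Feature matrix contains missing values.",
          class = "pascrosstalk_input_error")
  }
  fit <- seeded_kmeans(x, k, seed)
  raw <- tibble(sample_id = rownames(x),
                group = as.character(fit$cluster))
  summ <- km_group_summary(raw, survival)
  # order clusters best outcome first: higher KM median (NA = never
  # reached = best), then higher restricted mean
  med <- ifelse(is.na(summ$median_survival), Inf, summ$median_survival)
  ord <- order(-med, -summ$rmean)
  relabel <- setNames(paste0("G", seq_len(k)), summ$group[ord])
  out <- tibble(
    sample_id = raw$sample_id,
    group = factor(unname(relabel[raw$group]),
                   levels = paste0("G", seq_len(k))))
  class(out) <- c("subtype_labels", class(out))
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  attr(out, "feature_ids") <- rownames(features)
  summ$group <- unname(relabel[summ$group])
  attr(out, "group_summary") <- arrange(summ, .data$group)
  out
}

#' @export
print.subtype_labels <- function(x, ...) {
  cat("# subtype_labels: ", nrow(x), " samples, k = ",
      attr(x, "k") %||% length(levels(x$group)), "\n", sep = "")
  NextMethod()
}

cv_cluster_metrics <- function(x, surv, k, seed, n_folds = 5) {
  n <- nrow(x)
  folds <- withr::with_seed(seed, rep_len(seq_len(n_folds), n)[sample(n)])
  horizon <- median(surv$time)
  pooled <- map(seq_len(n_folds), function(f) {
    tr <- folds != f
    fit <- seeded_kmeans(x[tr, , drop = FALSE], k, seed + f)
    # anchor cluster names to the training folds' outcome
    train_groups <- as.character(fit$cluster)
    summ <- km_group_summary(
      tibble(sample_id = rownames(x)[tr], group = train_groups),
      surv)
    med <- ifelse(is.na(summ$median_survival), Inf, summ$median_survival)
    relabel <- setNames(paste0("G", seq_len(k)),
                        summ$group[order(-med, -summ$rmean)])
    d2 <- apply(fit$centers, 1, function(ct) {
      rowSums((x[!tr, , drop = FALSE] -
                 matrix(ct, sum(!tr), ncol(x), byrow = TRUE))^2)
    })
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    test_groups <- relabel[as.character(max.col(-d2, ties.method = "first"))]
    train_df <- tibble(group = factor(relabel[train_groups],
                                      levels = paste0("G", seq_len(k))),
                       time = surv$time[tr], event = surv$event[tr])
    cfit <- survival::coxph(survival::Surv(time, event) ~ group,
                            data = train_df, model = TRUE)
    test_df <- tibble(sample_id = rownames(x)[!tr],
                      group = factor(unname(test_groups),
                                     levels = paste0("G", seq_len(k))),
                      time = surv$time[!tr], event = surv$event[!tr])
    test_df$risk <- predict(cfit, newdata = test_df, type = "lp")
    sfit <- survival::survfit(cfit, newdata = test_df)
    test_df$surv_prob <- as.numeric(
      summary(sfit, times = horizon, extend = TRUE)$surv)
    test_df$fold <- f
    test_df
  }) |>
    bind_rows()
  per_fold <- pooled |>
    group_by(.data$fold) |>
    dplyr::group_modify(function(d, key) {
      conc <- survival::concordance(
        survival::Surv(time, event) ~ risk, data = d, reverse = TRUE)
      dd <- droplevels(d)
      lp <- if (nlevels(dd$group) < 2) 1 else {
        sd_test <- survival::survdiff(
          survival::Surv(time, event) ~ group, data = dd)
        pchisq(sd_test$chisq, df = nlevels(dd$group) - 1,
               lower.tail = FALSE)
      }
      tibble(c_index = unname(conc$concordance),
             brier = ipcw_brier(d, d$surv_prob, horizon),
             neglog_p = -log10(max(lp, .Machine$double.xmin)))
    }) |>
    ungroup()
  mutate(per_fold, k = k)
}

#' Choose the cluster number by survival-metric majority vote
#'
#' For every candidate k, the cluster label is evaluated as a survival
#' risk factor by C-index, Brier score and log-rank p. The three metrics
#' are computed out-of-fold (5-fold: clusters fit on the training folds,
#' held-out samples assigned to the nearest centroid, Cox coefficients fit
#' on the training labels) because in-sample versions improve
#' mechanically with every extra cluster, and each metric is scored with
#' the one-standard-error parsimony rule: the smallest k whose mean
#' out-of-fold value lies within one fold standard error of the best
#' candidate wins that metric. The chosen k is the candidate winning the
#' most of the three metrics (higher C-index, lower Brier, lower log-rank
#' p), with remaining ties resolved to the smaller k. Candidates that
#' cannot be clustered are skipped with a warning.
#'
#' @inheritParams cluster_samples
#' @param k_candidates Integer candidates, subset of 2..10.
#' @return The chosen k (integer).
#' @export
choose_k <- function(features, survival, k_candidates = 2:4, seed = 1) {
  if (inherits(survival, "cohort")) survival <- survival$survival
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (!all(k_candidates %in% 2:10)) {
    abort("k_candidates must lie in 2..10.",
          class = "pascrosstalk_input_error")
  }
  x <- t(unclass(features))
  surv <- as_tibble(survival)
  surv <- surv[match(rownames(x), surv$sample_id), ]
  if (anyNA(surv$time)) {
    abort("Every sample needs a survival record.",
          class = "pascrosstalk_input_error")
  }
  per_fold <- map(k_candidates, function(k) {
    tryCatch(
      cv_cluster_metrics(x, surv, k, seed),
      error = function(e) {
        warn(sprintf("k = %d skipped: %s", k, conditionMessage(e)))
        NULL
      })
  }) |>
    bind_rows()
  if (nrow(per_fold) == 0) {
    abort("No candidate k could be clustered.",
          class = "pascrosstalk_cluster_error")
  }
  ks <- sort(unique(per_fold$k))
  if (length(ks) == 1) return(ks)
  summ <- per_fold |>
    group_by(.data$k) |>
    summarise(dplyr::across(c("c_index", "brier", "neglog_p"),
                            list(mean = mean, se = ~ sd(.x) / sqrt(n()))),
              .groups = "drop") |>
    arrange(.data$k)
  # one-SE rule per metric: smallest k within one SE of the best mean
  one_se_winner <- function(mu, se, maximize) {
    if (maximize) {
      best <- which.max(mu)
      min(which(mu >= mu[best] - se[best]))
    } else {
      best <- which.min(mu)
      min(which(mu <= mu[best] + se[best]))
    }
  }
  wins <- integer(length(ks))
  for (w in c(one_se_winner(summ$c_index_mean, summ$c_index_se, TRUE),
              one_se_winner(summ$brier_mean, summ$brier_se, FALSE),
              one_se_winner(summ$neglog_p_mean, summ$neglog_p_se, TRUE))) {
    wins[w] <- wins[w] + 1L
  }
  ks[order(-wins, ks)][1]
}
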