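join_labels_survival <- function(labels, survival) {
  if (inherits(survival, "cohort")) survival <- survival$survival
  df <- left_join(as_tibble(labels), as_tibble(survival), by = "sample_id")
  if (any(is.na(df$time))) {
    abort("Every labelled sample needs a survival record.",
          class = "pascrosstalk_input_error")
  }
  df$group <- factor(df$group)
  df
}

#' Fit a training risk reference from subtype labels
#'
#' Fits the Cox proportional-hazards model with the group label as sole
#' covariate on training data. The returned reference carries the fitted
#' coefficients and baseline so that [evaluate()] on a transferred cohort
#' can score risk with the training model instead of refitting.
#'
#' @param labels A `subtype_labels` tibble for the training samples.
#' @param survival The training survival table (or [new_cohort()]).
#' @return A `risk_reference` object.
#' @export
fit_risk_reference <- function(labels, survival) {
  df <- join_labels_survival(labels, survival)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ group, data = df, model = TRUE)
  structure(list(fit = fit, levels = levels(df$group)),
            class = "risk_reference")
}

# left-continuous censoring-survival G(t-) evaluated by step function
censoring_survival <- function(df) {
  cfit <- survival::survfit(
    survival::Surv(time, 1 - event) ~ 1, data = df)
  function(t, left = FALSE) {
    tt <- if (left) t - sqrt(.Machine$double.eps) * (1 + abs(t)) else t
    idx <- findInterval(tt, cfit$time)
    ifelse(idx == 0, 1, cfit$surv[pmax(idx, 1)])
  }
}

ipcw_brier <- function(df, surv_prob, horizon) {
  G <- censoring_survival(df)
  died_before <- df$time <= horizon & df$event == 1
  at_risk <- df$time > horizon
  w <- numeric(nrow(df))
  w[died_before] <- 1 / pmax(G(df$time[died_before], left = TRUE), 1e-8)
  w[at_risk] <- 1 / pmax(G(horizon), 1e-8)
  err <- numeric(nrow(df))
  err[died_before] <- (0 - surv_prob[died_before])^2
  err[at_risk] <- (1 - surv_prob[at_risk])^2
  mean(w * err)
}

#' Evaluate subtype labels as a survival risk predictor
#'
#' Treats the group label as the risk factor of a Cox model and reports the
#' three standard metrics: Harrell's C-index of the Cox risk score over
#' comparable pairs, the inverse-probability-of-censoring-weighted Brier
#' score of the model's predicted survival at a horizon (default: median
#' observed follow-up of the evaluated samples), and the log-rank test
#' p-value between the groups. The Cox coefficients come from
#' `train_reference` when given (cross-cohort transfer) and are otherwise
#' refit on the evaluated data. If only one group is present the report is
#' marked partial: C-index and log-rank p are undefined.
#'
#' @param labels A `subtype_labels` tibble.
#' @param survival Survival table (or [new_cohort()]) covering the
#'   labelled samples.
#' @param train_reference Optional [fit_risk_reference()] from the
#'   training cohort.
#' @param horizon Optional Brier horizon (same time unit as `survival`).
#' @return A one-row `evaluation_report` tibble: `n`, `n_events`,
#'   `c_index`, `brier`, `brier_horizon`, `logrank_p`, `partial`,
#'   `reason`.
#' @export
evaluate <- function(labels, survival, train_reference = NULL,
                     horizon = NULL) {
  df <- join_labels_survival(labels, survival)
  if (nrow(df) == 0 || sum(df$event) < 1) {
    abort("Evaluation needs at least one observed event.",
          class = "pascrosstalk_input_error")
  }
  if (is.null(horizon)) horizon <- median(df$time)
  present <- unique(as.character(df$group))
  partial <- length(present) < 2
  reason <- if (partial) "only one group present" else NA_character_

  c_index <- NA_real_
  logrank_p <- NA_real_
  brier <- NA_real_

  if (!is.null(train_reference)) {
    stopifnot(inherits(train_reference, "risk_reference"))
    fit <- train_reference$fit
    df$group <- factor(as.character(df$group),
                       levels = train_reference$levels)
  } else if (!partial) {
    fit <- survival::coxph(
      survival::Surv(time, event) ~ group, data = df, model = TRUE)
  } else {
    fit <- NULL
  }

  if (!partial) {
    risk <- predict(fit, newdata = df, type = "lp")
    conc <- survival::concordance(
      survival::Surv(time, event) ~ risk, data = df, reverse = TRUE)
    c_index <- unname(conc$concordance)
    sd_test <- survival::survdiff(
      survival::Surv(time, event) ~ group, data = df)
    logrank_p <- pchisq(sd_test$chisq, df = length(present) - 1,
                        lower.tail = FALSE)
  }
  if (!is.null(fit)) {
    sfit <- survival::survfit(fit, newdata = df)
    ssum <- summary(sfit, times = horizon, extend = TRUE)
    surv_prob <- as.numeric(ssum$surv)
    if (length(surv_prob) == nrow(df)) {
      brier <- ipcw_brier(df, surv_prob, horizon)
    }
  }

  out <- tibble(n = nrow(df), n_events = sum(df$event),
                c_index = c_index, brier = brier,
                brier_horizon = horizon, logrank_p = logrank_p,
                partial = partial, reason = reason)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report: n = %d (%d events), C-index = %s, Brier = %s @ t = %.3g, log-rank p = %s%s>\n",
    x$n, x$n_events,
    ifelse(is.na(x$c_index), "NA", sprintf("%.3f", x$c_index)),
    ifelse(is.na(x$brier), "NA", sprintf("%.3f", x$brier)),
    x$brier_horizon,
    ifelse(is.na(x$logrank_p), "NA", sprintf("%.3g", x$logrank_p)),
    ifelse(x$partial, paste0(" [partial: ", x$reason, "]"), "")))
  invisible(x)
}

#' @export
glance.evaluation_report <- function(x, ...) as_tibble(x)

#' Kaplan-Meier step tables (and optional files) per group
#'
#' Computes the product-limit survival estimate per group, including the
#' time-0 row at survival 1, and optionally writes the step table as TSV
#' and the curve plot to files.
#'
#' @param labels A `subtype_labels` tibble (all groups non-empty).
#' @param survival Survival table (or [new_cohort()]).
#' @param path Optional TSV output path for the step table.
#' @param plot_path Optional image path (passed to [ggplot2::ggsave()]).
#' @return Tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @export
km_curves <- function(labels, survival, path = NULL, plot_path = NULL) {
  df <- join_labels_survival(labels, survival)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(paste0("group=", levels(df$group)[1]), length(fit$time))
  } else {
    rep(names(fit$strata), fit$strata)
  }
  tab <- tibble(group = sub("^group=", "", strata),
                time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor,
                survival = fit$surv)
  zero <- tab |>
    group_by(.data$group) |>
    summarise(time = 0, n_risk = max(.data$n_risk), n_event = 0L,
              n_censor = 0L, survival = 1, .groups = "drop")
  tab <- bind_rows(zero, tab) |>
    arrange(.data$group, .data$time)
  if (!is.null(path)) {
    tryCatch(readr::write_tsv(tab, path, progress = FALSE),
             error = function(e) abort(
               paste0("Cannot write KM table to ", path),
               class = "pascrosstalk_io_error"))
  }
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, plot_km(labels, survival),
                    width = 6, height = 4)
  }
  tab
}

#' Kaplan-Meier plot of the risk groups
#'
#' @inheritParams km_curves
#' @return A ggplot object with one survival step curve per group.
#' @export
plot_km <- function(labels, survival) {
  tab <- km_curves(labels, survival)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}
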