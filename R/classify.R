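#' Stratified train/test split
#'
#' Partitions a cohort's samples into train and test sets at the given
#' ratio (default 4:1, i.e. a test fraction of 1/5 rounded to the nearest
#' integer), stratified jointly by subtype label and event indicator so
#' that both outcome and class balance carry over. If any joint stratum
#' has fewer than 5 samples, stratification falls back to the label alone
#' with a warning. Per-stratum test counts are apportioned by largest
#' remainder so the total test size is exact.
#'
#' @param samples Character vector of sample ids, or a data frame with a
#'   `sample_id` column.
#' @param strata Data frame with columns `sample_id`, `group` and
#'   (optionally) `event`.
#' @param ratio Train:test ratio as a length-2 numeric (default `c(4, 1)`).
#' @param seed Integer seed; the partition is deterministic given it.
#' @return List with character vectors `train` and `test`
#'   (disjoint, union = all samples).
#' @export
split_cohort <- function(samples, strata, ratio = c(4, 1), seed = 1) {
  if (is.data.frame(samples)) samples <- samples$sample_id
  samples <- as.character(samples)
  n <- length(samples)
  if (n < 5) {
    abort("Need at least 5 samples to split 4:1.",
          class = "pascrosstalk_input_error")
  }
  strata <- as_tibble(strata)
  if (!all(c("sample_id", "group") %in% names(strata))) {
    abort("strata needs columns sample_id and group.",
          class = "pascrosstalk_input_error")
  }
  strata <- strata[match(samples, strata$sample_id), ]
  if (anyNA(strata$group)) {
    abort("Every sample needs a stratum label.",
          class = "pascrosstalk_input_error")
  }
  key <- if ("event" %in% names(strata)) {
    paste(strata$group, strata$event, sep = "/")
  } else {
    as.character(strata$group)
  }
  if (min(table(key)) < 5 && "event" %in% names(strata)) {
    warn("A joint (group, event) stratum has fewer than 5 samples; stratifying by group only.")
    key <- as.character(strata$group)
  }
  test_frac <- ratio[2] / sum(ratio)
  n_test <- round(n * test_frac)
  counts <- table(key)
  exact <- counts * test_frac
  base <- floor(exact)
  remainder <- n_test - sum(base)
  frac <- exact - base
  ord <- order(-frac, names(counts))
  extra <- integer(length(counts))
  if (remainder > 0) extra[ord[seq_len(remainder)]] <- 1L
  if (remainder < 0) {
    take_back <- order(frac, names(counts))
    take_back <- take_back[base[take_back] > 0]
    extra[take_back[seq_len(-remainder)]] <- -1L
  }
  per_stratum <- setNames(as.integer(base + extra), names(counts))
  test <- withr::with_seed(seed, {
    unlist(map(names(counts), function(s) {
      ids <- samples[key == s]
      sample(ids, per_stratum[[s]])
    }), use.names = FALSE)
  })
  list(train = setdiff(samples, test), test = test)
}

# ---- weak learners -------------------------------------------------------

fit_adaboost <- function(x, y, n_estimators, learning_rate) {
  # AdaBoost.M1 with depth-1 rpart stumps and a shrinkage factor on the
  # stage weights; y is a two-level factor
  lev <- levels(y)
  ynum <- ifelse(y == lev[2], 1, -1)
  df <- as.data.frame(x)
  w <- rep(1 / length(ynum), length(ynum))
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(
      yf ~ ., data = cbind(df, yf = factor(ynum, levels = c(-1, 1))),
      weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                                     xval = 0))
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != ynum])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ynum * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(stumps) == 0) {
    # no stump beat chance; fall back to the majority class
    return(list(levels = lev, stumps = list(), alphas = numeric(0),
                fallback = lev[which.max(table(y))]))
  }
  list(levels = lev, stumps = stumps, alphas = alphas, fallback = NULL)
}

predict_adaboost <- function(model, x) {
  df <- as.data.frame(x)
  if (length(model$stumps) == 0) {
    return(factor(rep(model$fallback, nrow(df)), levels = model$levels))
  }
  score <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.numeric(as.character(
      predict(model$stumps[[m]], df, type = "class")))
    score <- score + model$alphas[m] * pred
  }
  factor(ifelse(score >= 0, model$levels[2], model$levels[1]),
         levels = model$levels)
}

fit_gnb <- function(x, y, var_smoothing) {
  # Gaussian naive Bayes with additive variance smoothing proportional to
  # the largest feature variance (keeps near-constant features finite)
  lev <- levels(y)
  eps <- var_smoothing * max(apply(x, 2, var), .Machine$double.eps)
  stats_by_class <- map(lev, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    list(mean = colMeans(xc), var = apply(xc, 2, var) + eps,
         logprior = log(nrow(xc) / nrow(x)))
  })
  list(levels = lev, stats = setNames(stats_by_class, lev))
}

predict_gnb <- function(model, x) {
  ll <- map(model$stats, function(s) {
    rowSums(-0.5 * log(2 * pi * rep(s$var, each = nrow(x))) -
              0.5 * sweep(x, 2, s$mean)^2 /
              rep(s$var, each = nrow(x))) + s$logprior
  })
  ll <- do.call(cbind, ll)
  factor(model$levels[max.col(ll, ties.method = "first")],
         levels = model$levels)
}

# ---- grid search ---------------------------------------------------------

classifier_grid <- function(kind) {
  switch(kind,
         svm = tidyr::expand_grid(kernel = c("linear", "radial"),
                                  cost = c(0.1, 1, 10)),
         adaboost = tidyr::expand_grid(n_estimators = c(50L, 100L, 200L),
                                       learning_rate = c(0.1, 1.0)),
         gaussian = tibble(var_smoothing = c(1e-9, 1e-7, 1e-5)))
}

fit_one <- function(kind, x, y, params) {
  switch(kind,
         svm = e1071::svm(x, y, kernel = as.character(params$kernel),
                          cost = params$cost, scale = FALSE),
         adaboost = fit_adaboost(x, y, params$n_estimators,
                                 params$learning_rate),
         gaussian = fit_gnb(x, y, params$var_smoothing))
}

predict_one <- function(kind, fit, x) {
  switch(kind,
         svm = predict(fit, x),
         adaboost = predict_adaboost(fit, x),
         gaussian = predict_gnb(fit, x))
}

stratified_folds <- function(y, n_folds, seed, max_tries = 20) {
  n <- length(y)
  for (try in seq_len(max_tries)) {
    folds <- withr::with_seed(seed + try - 1L, {
      f <- integer(n)
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      f
    })
    ok <- all(map_lgl(seq_len(n_folds), function(k) {
      length(unique(y[folds != k])) == nlevels(y) && sum(folds == k) > 0
    }))
    if (ok) return(folds)
  }
  abort("Could not build stratified folds with every class in every training fold.",
        class = "pascrosstalk_input_error")
}

#' Train the subtype classifier with cross-validated grid search
#'
#' Trains one of three classifier families on the sub-pathway PAS features
#' of the training samples, choosing hyperparameters by mean 10-fold
#' stratified cross-validated accuracy over a fixed grid, then refitting on
#' the full training set with the winners. The grids are fixed defaults:
#' SVM kernel {linear, rbf} x cost {0.1, 1, 10}; AdaBoost stumps
#' {50, 100, 200} x learning rate {0.1, 1.0}; Gaussian naive Bayes
#' variance smoothing {1e-9, 1e-7, 1e-5}. Ties go to the earlier grid row,
#' so the choice is deterministic given the seed.
#'
#' @param features A `pas_matrix` (features x samples) restricted to the
#'   training samples.
#' @param labels A `subtype_labels` tibble covering those samples.
#' @param kind `"svm"`, `"adaboost"` or `"gaussian"` (Gaussian naive
#'   Bayes).
#' @param seed Integer seed for fold assignment.
#' @param n_folds Cross-validation folds (default 10).
#' @return A `risk_model`: list with the fitted classifier, `kind`,
#'   `feature_ids` (fixed order), `levels`, chosen `hyperparameters`, the
#'   CV `grid` tibble and `seed`. [tidy()] returns the grid with CV
#'   accuracies, [glance()] a one-row summary.
#' @export
train_classifier <- function(features, labels, kind = c("svm", "adaboost",
                                                        "gaussian"),
                             seed = 1, n_folds = 10) {
  kind <- arg_match(kind)
  stopifnot(inherits(features, "pas_matrix"))
  x <- t(unclass(features))
  labels <- as_tibble(labels)
  idx <- match(rownames(x), labels$sample_id)
  if (anyNA(idx)) {
    abort("Every feature-matrix sample needs a label.",
          class = "pascrosstalk_input_error")
  }
  y <- droplevels(factor(labels$group[idx]))
  if (nlevels(y) < 2 || min(table(y)) < 2) {
    abort("Need at least 2 samples in each of at least 2 classes.",
          class = "pascrosstalk_input_error")
  }
  grid <- classifier_grid(kind)
  folds <- stratified_folds(y, min(n_folds, min(table(y))), seed)
  n_folds_eff <- max(folds)
  cv_acc <- map_dbl(seq_len(nrow(grid)), function(g) {
    params <- grid[g, ]
    accs <- map_dbl(seq_len(n_folds_eff), function(k) {
      tr <- folds != k
      fit <- fit_one(kind, x[tr, , drop = FALSE], droplevels(y[tr]), params)
      pred <- predict_one(kind, fit, x[!tr, , drop = FALSE])
      mean(as.character(pred) == as.character(y[!tr]))
    })
    mean(accs)
  })
  best <- which.max(cv_acc)  # ties -> earliest grid row
  fit <- fit_one(kind, x, y, grid[best, ])
  structure(
    list(kind = kind, fit = fit,
         feature_ids = rownames(features),
         levels = levels(y),
         hyperparameters = as.list(grid[best, ]),
         grid = mutate(grid, cv_accuracy = cv_acc),
         cv_accuracy = cv_acc[best],
         n_folds = n_folds_eff, seed = seed),
    class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              map_chr(x$hyperparameters, ~ format(.x)), sep = "=",
              collapse = ", ")
  cat(sprintf("<risk_model %s: %d features, CV accuracy %.3f (%s)>\n",
              x$kind, length(x$feature_ids), x$cv_accuracy, hp))
  invisible(x)
}

#' @rdname train_classifier
#' @param x A `risk_model`.
#' @param ... Ignored.
#' @export
tidy.risk_model <- function(x, ...) x$grid

#' @rdname train_classifier
#' @export
glance.risk_model <- function(x, ...) {
  tibble(kind = x$kind, n_features = length(x$feature_ids),
         cv_accuracy = x$cv_accuracy, n_folds = x$n_folds, seed = x$seed)
}

#' Transfer subtype calls to a new cohort
#'
#' Predicts G1/G2 membership for new samples from their sub-pathway PAS
#' (recomputed within the target cohort; the median-split score makes the
#' transfer robust to monotone platform effects). The G1/G2 semantics are
#' carried over from training — groups are never re-anchored on the target
#' cohort's survival. The feature rows must match the training features
#' exactly; missing rows raise an error rather than being imputed.
#'
#' @param model A `risk_model` from [train_classifier()].
#' @param features A `pas_matrix` for the target cohort containing every
#'   training feature row.
#' @return A `subtype_labels` tibble (`sample_id`, `group`).
#' @export
predict_groups <- function(model, features) {
  stopifnot(inherits(model, "risk_model"), inherits(features, "pas_matrix"))
  missing_ids <- setdiff(model$feature_ids, rownames(features))
  if (length(missing_ids) > 0) {
    abort(paste0("Feature matrix is missing training feature(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "pascrosstalk_input_error")
  }
  x <- t(unclass(features)[model$feature_ids, , drop = FALSE])
  if (ncol(features) > 0) {
    pred <- predict_one(model$kind, model$fit, x)
    out <- tibble(sample_id = colnames(features),
                  group = factor(as.character(pred), levels = model$levels))
  } else {
    out <- tibble(sample_id = character(0),
                  group = factor(character(0), levels = model$levels))
  }
  class(out) <- c("subtype_labels", class(out))
  attr(out, "k") <- length(model$levels)
  out
}
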