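make_labels <- function(sample_id, group) {
  out <- tibble::tibble(sample_id = sample_id,
                        group = factor(group, levels = c("G1", "G2")))
  class(out) <- c("subtype_labels", class(out))
  out
}

test_that("random labels score at chance and null groups are non-significant", {
  withr::with_seed(77, {
    n <- 500
    surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           time = rexp(n, 0.1),
                           event = rbinom(n, 1, 0.7))
    labels <- make_labels(surv$sample_id,
                          sample(c("G1", "G2"), n, replace = TRUE))
  })
  rep <- evaluate(labels, surv)
  expect_gte(rep$c_index, 0.45)
  expect_lte(rep$c_index, 0.55)
  expect_true(rep$brier >= 0 && rep$brier <= 1)

  nonsig <- 0L
  for (seed in 1:20) {
    withr::with_seed(seed, {
      surv_i <- tibble::tibble(sample_id = sprintf("s%03d", 1:120),
                               time = rexp(120, 0.1),
                               event = rbinom(120, 1, 0.8))
      lab_i <- make_labels(surv_i$sample_id,
                           sample(c("G1", "G2"), 120, replace = TRUE))
    })
    rep_i <- evaluate(lab_i, surv_i)
    nonsig <- nonsig + as.integer(rep_i$logrank_p > 0.05)
  }
  expect_gte(nonsig, 18L)  # >= 90% of 20 seeds
})

test_that("a strong group effect yields high C-index and small log-rank p", {
  withr::with_seed(13, {
    n <- 200
    grp <- rep(c("G1", "G2"), each = n / 2)
    surv <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                           time = rexp(n, ifelse(grp == "G2", 0.5, 0.05)),
                           event = 1)
  })
  labels <- make_labels(surv$sample_id, grp)
  rep <- evaluate(labels, surv)
  # a two-level predictor at hazard ratio 10 tops out near C = 0.70
  expect_gt(rep$c_index, 0.65)
  expect_lt(rep$logrank_p, 1e-6)

  # the fitted model beats predicting the pooled KM curve for everyone
  fitKM <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  pooled <- summary(fitKM, times = rep$brier_horizon, extend = TRUE)$surv
  df <- dplyr::left_join(labels, surv, by = "sample_id")
  pooled_brier <- pascrosstalk:::ipcw_brier(df, rep(pooled, n),
                                            rep$brier_horizon)
  expect_lte(rep$brier, pooled_brier)
})

test_that("evaluation with a training reference transfers the risk direction", {
  withr::with_seed(29, {
    mk <- function(n, flip = FALSE) {
      grp <- rep(c("G1", "G2"), each = n / 2)
      rate <- if (flip) ifelse(grp == "G2", 0.05, 0.5) else
        ifelse(grp == "G2", 0.5, 0.05)
      tibble::tibble(sample_id = sprintf("x%03d_%d", 1:n, flip),
                     group = grp, time = rexp(n, rate), event = 1)
    }
    train <- mk(200)
    test <- mk(200)
  })
  ref <- fit_risk_reference(make_labels(train$sample_id, train$group),
                            train[, c("sample_id", "time", "event")])
  rep <- evaluate(make_labels(test$sample_id, test$group),
                  test[, c("sample_id", "time", "event")],
                  train_reference = ref)
  expect_gt(rep$c_index, 0.65)
  expect_false(rep$partial)
})

test_that("a single-group evaluation is marked partial", {
  surv <- tibble::tibble(sample_id = paste0("s", 1:10),
                         time = 1:10, event = rep(c(1, 0), 5))
  labels <- make_labels(surv$sample_id, rep("G1", 10))
  rep <- evaluate(labels, surv)
  expect_true(rep$partial)
  expect_true(is.na(rep$c_index) && is.na(rep$logrank_p))
})

test_that("Kaplan-Meier tables match closed forms", {
  # no events: flat curve at 1
  surv0 <- tibble::tibble(sample_id = paste0("s", 1:5),
                          time = 1:5, event = 0)
  tab0 <- km_curves(make_labels(surv0$sample_id, rep("G1", 5)), surv0)
  expect_true(all(tab0$survival == 1))
  expect_identical(tab0$survival[tab0$time == 0], 1)

  # single event in a group of n drops survival to (n-1)/n
  surv1 <- tibble::tibble(sample_id = paste0("s", 1:8),
                          time = c(3, rep(9, 7)), event = c(1, rep(0, 7)))
  tab1 <- km_curves(make_labels(surv1$sample_id, rep("G1", 8)), surv1)
  expect_equal(min(tab1$survival), 7 / 8)
})

test_that("km_curves writes the step table and plot_km returns a ggplot", {
  withr::with_seed(3, {
    surv <- tibble::tibble(sample_id = paste0("s", 1:30),
                           time = rexp(30, 0.2),
                           event = rbinom(30, 1, 0.7))
    labels <- make_labels(surv$sample_id,
                          rep(c("G1", "G2"), 15))
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- km_curves(labels, surv, path = path)
  expect_true(file.exists(path))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_s3_class(plot_km(labels, surv), "ggplot")
})

test_that("evaluate validates its inputs", {
  surv <- tibble::tibble(sample_id = paste0("s", 1:4),
                         time = 1:4, event = 0)
  labels <- make_labels(surv$sample_id, c("G1", "G2", "G1", "G2"))
  expect_error(evaluate(labels, surv), class = "pascrosstalk_input_error")
  expect_error(
    evaluate(make_labels("zz", "G1"), surv),
    class = "pascrosstalk_input_error")
})
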