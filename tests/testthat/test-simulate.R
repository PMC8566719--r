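test_that("simulated collections honour the overlap specification", {
  cfg <- sim_config(n_pathways = 6, n_genes = 200,
                    pathway_size_range = c(8, 12),
                    overlap_spec = data.frame(a = "P01", b = "P02",
                                              shared = 3L),
                    seed = 11)
  gs <- gene_sets(simulate_collection(cfg))
  expect_length(gs, 6)
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (j <= i) next
      expected <- if (i == 1 && j == 2) 3L else 0L
      expect_identical(length(intersect(gs[[i]], gs[[j]])), expected)
    }
  }

  cfg0 <- sim_config(n_pathways = 4, n_genes = 200,
                     overlap_spec = data.frame(a = character(),
                                               b = character(),
                                               shared = integer()),
                     planted_pair = c("P01", "P02"))
  expect_error(ground_truth(cfg0), class = "pascrosstalk_config_error")
  gs0 <- gene_sets(simulate_collection(cfg0))
  expect_identical(length(Reduce(intersect, gs0)), 0L)
  expect_identical(sum(lengths(gs0)),
                   length(unique(unlist(gs0))))  # pairwise disjoint

  expect_error(
    simulate_collection(
      sim_config(n_pathways = 3, pathway_size_range = c(4, 4),
                 overlap_spec = data.frame(a = "P01", b = "P02",
                                           shared = 5L))),
    class = "pascrosstalk_config_error")
})

test_that("identical configs give bit-identical data", {
  cfg <- quick_config(seed = 3, n = 50)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(gene_sets(a$collection), gene_sets(b$collection))
  expect_identical(a$cohorts[["C2"]]$expression,
                   b$cohorts[["C2"]]$expression)
  expect_identical(a$cohorts[["C2"]]$survival, b$cohorts[["C2"]]$survival)
})

test_that("censoring is calibrated and switches off at rate 0", {
  cfg <- quick_config(seed = 5, n = 400, n_cohorts = 1, censor = 0)
  co <- simulate_cohort(cfg, simulate_collection(cfg), 1)
  expect_true(all(co$survival$event == 1))

  for (rate in c(0.2, 0.5)) {
    cfg <- quick_config(seed = 5, n = 400, n_cohorts = 1, censor = rate)
    co <- simulate_cohort(cfg, simulate_collection(cfg), 1)
    expect_lt(abs(mean(co$survival$event == 0) - rate), 0.05)
  }
})

test_that("a null effect leaves event times uncorrelated with the latent", {
  cfg <- sim_config(n_cohorts = 1, samples_per_cohort = 500,
                    n_genes = 200, n_pathways = 5,
                    pathway_size_range = c(5, 8),
                    overlap_spec = data.frame(a = "P01", b = "P02",
                                              shared = 3L),
                    log_hazard_coeff = 0, censor_rate = 0, seed = 21)
  co <- simulate_cohort(cfg, simulate_collection(cfg), 1)
  a <- attr(co, "latent_activity")
  expect_lt(abs(cor(a, co$survival$time)), 0.1)
})

test_that("Cox on the generating latent recovers the planted hazard", {
  # oracle: standard Cox fit on the true latent activity itself
  hits <- 0L
  for (seed in 1:20) {
    cfg <- quick_config(seed = seed, coeff = 1.5, n = 300, n_cohorts = 1)
    co <- simulate_cohort(cfg, simulate_collection(cfg), 1)
    a <- attr(co, "latent_activity")
    fit <- survival::coxph(
      survival::Surv(co$survival$time, co$survival$event) ~ a)
    ok <- coef(fit) > 0 && summary(fit)$sctest["pvalue"] < 1e-3
    hits <- hits + as.integer(ok)
  }
  expect_gte(hits, 19L)  # >= 95% of 20 seeds
})

test_that("the platform distortion is monotone and PAS-invariant", {
  cfg_raw <- quick_config(seed = 9, n = 80, n_cohorts = 2, distort = FALSE)
  cfg_dis <- quick_config(seed = 9, n = 80, n_cohorts = 2, distort = TRUE)
  coll <- simulate_collection(cfg_raw)
  raw <- simulate_cohort(cfg_raw, coll, 2)
  dis <- simulate_cohort(cfg_dis, coll, 2)
  expect_false(identical(raw$expression, dis$expression))
  # strictly increasing distortion preserves within-gene sample ranks
  expect_identical(t(apply(raw$expression[1:10, ], 1, rank)),
                   t(apply(dis$expression[1:10, ], 1, rank)))
  expect_equal(unclass(compute_pas(raw, coll)),
               unclass(compute_pas(dis, coll)))
})

test_that("ground truth exposes the planted sub-pathway", {
  cfg <- quick_config(seed = 2)
  coll <- simulate_collection(cfg)
  truth <- ground_truth(cfg, coll)
  expect_identical(truth$part, "intersection")
  expect_gte(truth$n_genes, 3L)
  sets <- gene_sets(coll)
  expect_true(all(truth$genes[[1]] %in%
                    union(sets[[truth$parent_a]], sets[[truth$parent_b]])))
  expect_setequal(truth$genes[[1]],
                  intersect(sets[[truth$parent_a]],
                            sets[[truth$parent_b]]))

  cfg_b <- sim_config(n_pathways = 5, n_genes = 200,
                      overlap_spec = data.frame(a = "P02", b = "P04",
                                                shared = 4L),
                      planted_part = "B_unique", seed = 4)
  truth_b <- ground_truth(cfg_b)
  sets_b <- gene_sets(simulate_collection(cfg_b))
  expect_setequal(truth_b$genes[[1]],
                  setdiff(sets_b[["P04"]], sets_b[["P02"]]))
})

test_that("cohort_index outside the configured range is rejected", {
  cfg <- quick_config(seed = 1, n_cohorts = 2, n = 50)
  coll <- simulate_collection(cfg)
  expect_error(simulate_cohort(cfg, coll, 3),
               class = "pascrosstalk_config_error")
})
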