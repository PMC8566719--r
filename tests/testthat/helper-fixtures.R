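# Small deterministic fixtures shared across test files.

toy_expression <- function() {
  m <- rbind(
    gA = c(1, 2, 3, 4),
    gB = c(1, 4, 2, 5),
    gC = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  m
}

toy_cohort <- function(time = c(5, 4, 3, 2), event = c(1, 1, 0, 1)) {
  new_cohort("TOY", toy_expression(),
             tibble::tibble(sample_id = paste0("s", 1:4),
                            time = time, event = event),
             quiet = TRUE)
}

# cohort with n samples of pure-noise expression and independent survival
noise_cohort <- function(n = 40, n_genes = 20, seed = 1, censor = 0.25) {
  withr::with_seed(seed, {
    expr <- matrix(rnorm(n_genes * n), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                   sprintf("s%03d", seq_len(n))))
    surv <- tibble::tibble(
      sample_id = colnames(expr),
      time = rexp(n, rate = 0.2),
      event = rbinom(n, 1, 1 - censor))
    new_cohort("NOISE", expr, surv, quiet = TRUE)
  })
}

# pas_matrix built directly from a numeric matrix (bypasses a cohort)
fake_pas <- function(values, cohort_id = "FAKE") {
  pascrosstalk:::new_pas_matrix(
    values, cohort_id,
    stats::setNames(rep(1L, nrow(values)), rownames(values)))
}

# scaled-down simulator configs used across tests
quick_config <- function(seed = 1, coeff = 1.5, n = 120, n_cohorts = 3,
                         distort = TRUE, censor = 0.3) {
  sim_config(n_cohorts = n_cohorts, samples_per_cohort = n,
             n_genes = 300, n_pathways = 10,
             pathway_size_range = c(8, 15),
             overlap_spec = data.frame(a = "P01", b = "P02", shared = 5L),
             log_hazard_coeff = coeff, censor_rate = censor,
             distort = distort, seed = seed)
}

# gene-set match irrespective of which parent was called A or B
same_subpathway <- function(truth, subpath_genes) {
  any(vapply(subpath_genes, function(g) setequal(g, truth$genes[[1]]),
             logical(1)))
}

expect_identical_partition <- function(pred, truth) {
  tab <- table(pred, truth)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
}
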