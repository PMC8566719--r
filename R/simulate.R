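#' Configure the multi-cohort survival simulator
#'
#' The simulator emulates the statistical structure the pipeline assumes:
#' several expression cohorts of a few hundred samples, a gene-set
#' collection with controlled pairwise overlaps, right-censored survival
#' whose hazard is log-linear in a latent activity, and a strictly
#' increasing per-cohort distortion of all expression values that mimics
#' platform differences (RNA-seq vs microarray) without ever changing
#' within-cohort ranks.
#'
#' Exactly one planted effect drives the data: samples draw a latent
#' activity `a ~ N(0, 1)`; genes in the planted sub-pathway (by default the
#' intersection of the first overlapping pair) have their mean shifted by
#' `a`; all other genes are independent standard normal noise. Event times
#' are exponential with hazard `baseline_hazard * exp(log_hazard_coeff * a)`
#' and an independent exponential censoring time is calibrated so the
#' expected censoring fraction equals `censor_rate`.
#'
#' @param n_cohorts Number of cohorts to simulate.
#' @param samples_per_cohort Samples in each cohort.
#' @param n_genes Total genes in the expression universe.
#' @param n_pathways Number of pathways in the collection.
#' @param pathway_size_range Integer `(min, max)` pathway sizes, min >= 3.
#' @param overlap_spec Data frame with columns `a`, `b` (pathway ids of an
#'   overlapping pair) and `shared` (shared-gene count); unlisted pairs are
#'   disjoint. Defaults to one pair, `P01`/`P02`, sharing 6 genes.
#' @param planted_pair Character pair naming the parents of the planted
#'   sub-pathway (must appear in `overlap_spec`).
#' @param planted_part Which part carries the signal: `"intersection"`,
#'   `"A_unique"` or `"B_unique"`.
#' @param log_hazard_coeff Effect of the latent activity on the log hazard;
#'   0 simulates the null.
#' @param censor_rate Target censoring fraction in `[0, 1)`.
#' @param baseline_hazard Baseline exponential hazard (per time unit).
#' @param distort Apply the per-cohort monotone platform distortion.
#' @param seed Integer seed; identical configs give bit-identical data.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 4,
                       samples_per_cohort = 300,
                       n_genes = 2000,
                       n_pathways = 50,
                       pathway_size_range = c(10, 30),
                       overlap_spec = NULL,
                       planted_pair = NULL,
                       planted_part = "intersection",
                       log_hazard_coeff = 1.5,
                       censor_rate = 0.3,
                       baseline_hazard = 0.1,
                       distort = TRUE,
                       seed = 1) {
  if (is.null(overlap_spec)) {
    overlap_spec <- tibble(a = "P01", b = "P02", shared = 6L)
  }
  overlap_spec <- as_tibble(overlap_spec)
  if (nrow(overlap_spec) > 0 &&
      !all(c("a", "b", "shared") %in% names(overlap_spec))) {
    abort("overlap_spec needs columns a, b, shared.",
          class = "pascrosstalk_config_error")
  }
  if (is.null(planted_pair)) {
    planted_pair <- if (nrow(overlap_spec) > 0) {
      c(overlap_spec$a[1], overlap_spec$b[1])
    } else {
      c(NA_character_, NA_character_)
    }
  }
  planted_part <- arg_match0(planted_part,
                             c("intersection", "A_unique", "B_unique"))
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    samples_per_cohort = as.integer(samples_per_cohort),
    n_genes = as.integer(n_genes),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    overlap_spec = overlap_spec,
    planted_pair = as.character(planted_pair),
    planted_part = planted_part,
    log_hazard_coeff = as.numeric(log_hazard_coeff),
    censor_rate = as.numeric(censor_rate),
    baseline_hazard = as.numeric(baseline_hazard),
    distort = isTRUE(distort),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cohorts < 1 || cfg$samples_per_cohort < 2 ||
      cfg$n_genes < 1 || cfg$n_pathways < 1) {
    abort("Cohort, sample, gene and pathway counts must be positive.",
          class = "pascrosstalk_config_error")
  }
  if (cfg$pathway_size_range[1] < 3 ||
      cfg$pathway_size_range[2] < cfg$pathway_size_range[1]) {
    abort("pathway_size_range must satisfy 3 <= min <= max.",
          class = "pascrosstalk_config_error")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    abort("censor_rate must lie in [0, 1).",
          class = "pascrosstalk_config_error")
  }
  if (cfg$baseline_hazard <= 0) {
    abort("baseline_hazard must be positive.",
          class = "pascrosstalk_config_error")
  }
  invisible(cfg)
}

pathway_ids_for <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate a gene-set collection with controlled overlaps
#'
#' Draws `n_pathways` gene sets with sizes uniform in
#' `pathway_size_range`. Every pair listed in `overlap_spec` shares exactly
#' its specified number of genes; all unlisted pairs are disjoint.
#'
#' @param config A [sim_config()].
#' @return A [gene_set_collection()].
#' @export
simulate_collection <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    ids <- pathway_ids_for(config$n_pathways)
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]),
                    config$n_pathways, replace = TRUE)
    names(sizes) <- ids
    ov <- config$overlap_spec
    if (nrow(ov) > 0) {
      if (!all(c(ov$a, ov$b) %in% ids)) {
        abort("overlap_spec refers to pathway ids outside the collection.",
              class = "pascrosstalk_config_error")
      }
      shared_per_pathway <- tapply(
        rep(ov$shared, 2), c(ov$a, ov$b), sum)
      over <- names(shared_per_pathway)[
        shared_per_pathway > sizes[names(shared_per_pathway)]]
      if (length(over) > 0) {
        abort(paste0("overlap_spec infeasible: pathway ", over[1],
                     " would need more shared genes than its size."),
              class = "pascrosstalk_config_error")
      }
    }
    n_shared_total <- sum(ov$shared)
    n_unique_total <- sum(sizes) - 2 * n_shared_total
    if (n_shared_total + n_unique_total > config$n_genes) {
      abort("overlap_spec infeasible: gene universe too small for the requested sets.",
            class = "pascrosstalk_config_error")
    }
    pool <- sprintf("g%05d", seq_len(config$n_genes))
    pool <- sample(pool)
    sets <- setNames(vector("list", length(ids)), ids)
    cursor <- 0
    take <- function(k) {
      out <- pool[cursor + seq_len(k)]
      cursor <<- cursor + k
      out
    }
    # shared blocks first, then unique fill per pathway
    if (nrow(ov) > 0) {
      for (i in seq_len(nrow(ov))) {
        g <- take(ov$shared[i])
        sets[[ov$a[i]]] <- c(sets[[ov$a[i]]], g)
        sets[[ov$b[i]]] <- c(sets[[ov$b[i]]], g)
      }
    }
    for (id in ids) {
      need <- sizes[[id]] - length(sets[[id]])
      if (need > 0) sets[[id]] <- c(sets[[id]], take(need))
    }
    gene_set_collection(ids, sets, rep("simulated pathway", length(ids)))
  })
}

planted_parent_sets <- function(config, collection) {
  sets <- gene_sets(collection)
  pa <- config$planted_pair[1]
  pb <- config$planted_pair[2]
  if (is.na(pa) || !all(c(pa, pb) %in% names(sets))) {
    abort("Planted pair not present in the collection.",
          class = "pascrosstalk_config_error")
  }
  list(a = pa, b = pb, genes_a = sets[[pa]], genes_b = sets[[pb]])
}

#' Ground truth of the planted prognostic sub-pathway
#'
#' Reconstructs the collection deterministically from the config and
#' returns the planted sub-pathway (parents, part and gene set) so that
#' recovery tests can check it survives selection.
#'
#' @param config A [sim_config()].
#' @param collection Optional collection already generated from `config`
#'   (regenerated when omitted).
#' @return A one-row `subpathway_set` tibble.
#' @export
ground_truth <- function(config, collection = NULL) {
  if (is.null(collection)) collection <- simulate_collection(config)
  p <- planted_parent_sets(config, collection)
  shared <- intersect(p$genes_a, p$genes_b)
  genes <- switch(config$planted_part,
                  intersection = shared,
                  A_unique = setdiff(p$genes_a, shared),
                  B_unique = setdiff(p$genes_b, shared))
  if (length(genes) < 3) {
    abort("Planted target has fewer than 3 genes; increase the overlap or sizes.",
          class = "pascrosstalk_config_error")
  }
  new_subpathway_set(
    parent_a = p$a, parent_b = p$b,
    part = config$planted_part, genes = list(genes))
}

cohort_distortion <- function(cohort_index, seed) {
  # strictly increasing map x -> s1*x + s2*sign(x)*|x|^(1/3) + shift,
  # with s1, s2 > 0 drawn per cohort; mimics platform/scale differences
  withr::with_seed(seed + 7919L * cohort_index, {
    s1 <- runif(1, 0.5, 3)
    s2 <- runif(1, 0.2, 2)
    shift <- runif(1, -5, 5)
  })
  function(x) s1 * x + s2 * sign(x) * abs(x)^(1 / 3) + shift
}

#' Simulate one cohort under a config
#'
#' @param config A [sim_config()].
#' @param collection The collection from [simulate_collection()] with the
#'   same config.
#' @param cohort_index Which cohort (1-based) to generate; each index has
#'   its own RNG substream and its own monotone platform distortion.
#' @return A [new_cohort()] with attributes `latent_activity` (the true
#'   per-sample activity) attached for oracle checks.
#' @export
simulate_cohort <- function(config, collection, cohort_index) {
  validate_sim_config(config)
  if (cohort_index < 1 || cohort_index > config$n_cohorts) {
    abort(paste0("cohort_index must be in 1..", config$n_cohorts),
          class = "pascrosstalk_config_error")
  }
  truth <- ground_truth(config, collection)
  target_genes <- truth$genes[[1]]
  n <- config$samples_per_cohort
  cohort_id <- sprintf("C%d", cohort_index)
  withr::with_seed(config$seed + 104729L * cohort_index, {
    a <- rnorm(n)
    genes <- sort(unique(unlist(collection$genes, use.names = FALSE)))
    extra <- setdiff(sprintf("g%05d", seq_len(config$n_genes)), genes)
    genes <- c(genes, extra)
    expr <- matrix(rnorm(length(genes) * n), nrow = length(genes),
                   dimnames = list(genes, sprintf("%s_s%03d", cohort_id,
                                                  seq_len(n))))
    expr[target_genes, ] <- expr[target_genes, , drop = FALSE] +
      rep(a, each = length(target_genes))

    hazard <- config$baseline_hazard * exp(config$log_hazard_coeff * a)
    event_time <- rexp(n, rate = hazard)
    if (config$censor_rate > 0) {
      # P(C < T | h) = hc / (hc + h) for independent exponentials; solve
      # mean over the realized hazards for the target censoring fraction
      hc <- uniroot(function(lhc) {
        mean(exp(lhc) / (exp(lhc) + hazard)) - config$censor_rate
      }, lower = -30, upper = 30)$root
      cens_time <- rexp(n, rate = exp(hc))
    } else {
      cens_time <- rep(Inf, n)
    }
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)

    if (config$distort) {
      f <- cohort_distortion(cohort_index, config$seed)
      expr <- f(expr)
    }
    survival <- tibble(sample_id = colnames(expr), time = time,
                       event = event)
    cohort <- new_cohort(cohort_id, expr, survival, quiet = TRUE)
    attr(cohort, "latent_activity") <- setNames(a, colnames(expr))
    cohort
  })
}

#' Simulate a full multi-cohort study
#'
#' Convenience wrapper generating the collection, all cohorts and the
#' planted ground truth in one call.
#'
#' @param config A [sim_config()].
#' @return List with elements `collection`, `cohorts` (named list of
#'   [new_cohort()] objects) and `truth` (the planted sub-pathway).
#' @export
simulate_study <- function(config) {
  collection <- simulate_collection(config)
  cohorts <- map(seq_len(config$n_cohorts),
                 function(i) simulate_cohort(config, collection, i))
  names(cohorts) <- map_chr(cohorts, "cohort_id")
  list(collection = collection, cohorts = cohorts,
       truth = ground_truth(config, collection))
}
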