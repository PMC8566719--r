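test_that("degenerate activity rows get the sentinel p-value", {
  surv <- tibble::tibble(sample_id = paste0("s", 1:6),
                         time = c(3, 5, 2, 8, 1, 4),
                         event = c(1, 0, 1, 1, 0, 1))
  expect_warning(p <- pathway_survival_pvalue(rep(0.5, 6), surv),
                 class = "pascrosstalk_uninformative")
  expect_identical(p, 1)
  expect_warning(
    p0 <- pathway_survival_pvalue(rnorm(6),
                                  dplyr::mutate(surv, event = 0)),
    class = "pascrosstalk_uninformative")
  expect_identical(p0, 1)

  withr::with_seed(1, {
    p <- pathway_survival_pvalue(rnorm(6), surv)
  })
  expect_true(p > 0 && p <= 1)
})

test_that("combine_ranks orders by rank sum with deterministic tie-breaks", {
  # ranks (1,2), (2,1), (3,3); tie between A and B broken by min p (B wins)
  pv <- tibble::tibble(
    pathway_id = rep(c("A", "B", "C"), 2),
    cohort_id = rep(c("c1", "c2"), each = 3),
    p = c(0.01, 0.05, 0.50, 0.20, 0.002, 0.50))
  r <- combine_ranks(pv)
  expect_identical(r$pathway_id[order(r$combined_rank)], c("B", "A", "C"))
  expect_identical(sort(r$rank_c1), 1:3)

  # dominance: rank 1 everywhere -> combined rank 1
  expect_identical(r$pathway_id[r$combined_rank == 3], "C")

  # single cohort reduces to the p-value order
  one <- combine_ranks(dplyr::filter(pv, cohort_id == "c1"))
  expect_identical(one$pathway_id[order(one$combined_rank)],
                   c("A", "B", "C"))
})

test_that("combine_ranks is invariant to row order and monotone p transforms", {
  withr::with_seed(8, {
    pv <- tidyr::expand_grid(pathway_id = sprintf("P%02d", 1:12),
                             cohort_id = c("c1", "c2", "c3"))
    pv$p <- runif(nrow(pv))
    base <- combine_ranks(pv)
    shuffled <- pv[sample(nrow(pv)), ]
    shuffled$p <- sqrt(shuffled$p)  # strictly increasing on (0, 1]
    again <- combine_ranks(shuffled)
    expect_identical(
      base$pathway_id[order(base$combined_rank)],
      again$pathway_id[order(again$combined_rank)])
  })
})

test_that("combine_ranks validates its input", {
  pv <- tibble::tibble(pathway_id = c("A", "B", "A"),
                       cohort_id = c("c1", "c1", "c2"),
                       p = c(0.1, 0.2, 0.3))
  expect_error(combine_ranks(pv), class = "pascrosstalk_input_error")

  m <- matrix(runif(6), 3, 2,
              dimnames = list(c("A", "B", "C"), c("c1", "c2")))
  r <- combine_ranks(m)
  expect_identical(nrow(r), 3L)
})

test_that("select_top returns exactly n pathways in combined-rank order", {
  gs <- gene_set_collection(sprintf("P%02d", 1:8),
                            purrr::map(1:8, ~ sprintf("g%d_%d", .x, 1:4)))
  pv <- tibble::tibble(pathway_id = rep(gs$pathway_id, 2),
                       cohort_id = rep(c("c1", "c2"), each = 8),
                       p = (1:16) / 20)
  r <- combine_ranks(pv)
  top3 <- select_top(r, gs, n = 3)
  expect_identical(nrow(top3), 3L)
  expect_identical(top3$pathway_id,
                   r$pathway_id[order(r$combined_rank)][1:3])
  expect_identical(nrow(select_top(r, gs, n = 8)), 8L)
  expect_identical(select_top(r, gs, n = 1)$pathway_id,
                   r$pathway_id[r$combined_rank == 1])
  expect_error(select_top(r, gs, n = 9),
               class = "pascrosstalk_input_error")
  expect_warning(select_top(r, gs, n = 3, cohort_sizes = 300),
                 "N/log\\(N\\)")
})

test_that("crosstalk decomposition emits the three parts and filters by size", {
  gs <- gene_set_collection(
    c("A", "B"),
    list(paste0("g", 1:6), paste0("g", 4:9)))
  sp <- decompose_crosstalk(gs)
  expect_identical(nrow(sp), 3L)
  expect_identical(sp$part, c("intersection", "A_unique", "B_unique"))
  expect_setequal(sp$genes[[1]], paste0("g", 4:6))
  expect_setequal(sp$genes[[2]], paste0("g", 1:3))
  expect_setequal(sp$genes[[3]], paste0("g", 7:9))

  # overlap of 2 genes is no crosstalk at all
  gs2 <- gene_set_collection(c("A", "B"),
                             list(paste0("g", 1:6), paste0("g", 5:10)))
  expect_identical(nrow(decompose_crosstalk(gs2)), 0L)

  # nested pair: the empty A-unique part is dropped
  gs3 <- gene_set_collection(c("A", "B"),
                             list(paste0("g", 1:3), paste0("g", 1:6)))
  sp3 <- decompose_crosstalk(gs3)
  expect_identical(sp3$part, c("intersection", "B_unique"))
  expect_setequal(sp3$genes[[1]], paste0("g", 1:3))
  expect_setequal(sp3$genes[[2]], paste0("g", 4:6))
})

test_that("crosstalk parts partition the pair union, at most 3 per pair", {
  withr::with_seed(31, {
    for (case in 1:20) {
      k <- sample(3:6, 1)
      pool <- sprintf("g%03d", 1:60)
      gs <- gene_set_collection(
        sprintf("P%d", 1:k),
        purrr::map(1:k, ~ sample(pool, sample(6:15, 1))))
      sp <- decompose_crosstalk(gs, min_size = 1)
      expect_lte(nrow(sp), 3 * choose(k, 2))
      sets <- gene_sets(gs)
      for (pair in unique(paste(sp$parent_a, sp$parent_b))) {
        parts <- sp[paste(sp$parent_a, sp$parent_b) == pair, ]
        genes <- parts$genes
        # pairwise disjoint
        expect_identical(sum(lengths(genes)),
                         length(unique(unlist(genes))))
        # union equals the parent union (min_size 1 keeps all parts)
        expect_setequal(unlist(genes),
                        union(sets[[parts$parent_a[1]]],
                              sets[[parts$parent_b[1]]]))
      }
    }
  })
})

test_that("identical derived gene sets keep distinct provenance", {
  gs <- gene_set_collection(
    c("A", "B", "C"),
    list(paste0("g", 1:6), paste0("g", c(1:3, 7:9)),
         paste0("g", c(1:3, 10:12))))
  sp <- decompose_crosstalk(gs)
  inter <- sp[sp$part == "intersection", ]
  expect_identical(nrow(inter), 3L)  # A-B, A-C, B-C all share g1..g3
  expect_identical(anyDuplicated(inter$subpathway_id), 0L)
  purrr::walk(inter$genes, expect_setequal, paste0("g", 1:3))
})

test_that("sub-pathway screening adjusts within cohort and intersects cohorts", {
  cfg <- quick_config(seed = 12, coeff = 1.5, n = 150, n_cohorts = 2)
  st <- simulate_study(cfg)
  sp <- decompose_crosstalk(st$collection)
  sc <- score_subpathways(sp, st$cohorts, alpha = 0.01)
  td <- tidy(sc)
  expect_true(all(td$p_adj >= td$p))
  sel <- glance(sc)
  expect_identical(sel$n_selected, length(sc$selected))
  # selected implies significant in every cohort
  for (id in sc$selected) {
    expect_true(all(td$significant[td$subpathway_id == id]))
  }

  # Bonferroni with a single test leaves the p-value untouched
  one <- pascrosstalk:::new_subpathway_set(
    "P01", "P02", "intersection", list(st$truth$genes[[1]]))
  sc1 <- score_subpathways(one, st$cohorts[1], alpha = 0.01)
  expect_equal(sc1$scores$p_adj, sc1$scores$p)

  expect_error(score_subpathways(sp, list()),
               class = "pascrosstalk_input_error")
})
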