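# pascrosstalk

Pathway-crosstalk survival subtyping from rank-based pathway activity
scores, for bulk transcriptomic cohorts with right-censored survival.

Prognostic gene signatures built on absolute expression rarely survive the
jump between platforms (RNA-seq training data, microarray validation
cohorts). `pascrosstalk` implements a pathway-level pipeline that does:

1. **Pathway activity score (PAS).** For each gene, samples strictly above
   the within-cohort median expression vote +1, all others −1; the PAS of
   a pathway in a sample is the mean vote over its measured genes,

   PAS(P, s) = (1 / |P ∩ M|) Σ<sub>g ∈ P∩M</sub> v<sub>g</sub>(s),  v<sub>g</sub>(s) ∈ {−1, +1},

   bounded in [−1, +1] and invariant to any strictly increasing per-gene
   transformation — the property that makes cross-platform transfer work.
2. **Cross-cohort screening.** Per cohort, each pathway's PAS is tested
   with the score (log-rank) test of a univariate Cox regression; pathways
   are ranked per cohort and aggregated by sum of ranks (sure independence
   screening style), keeping the top n = 100.
3. **Crosstalk decomposition.** Every pathway pair sharing ≥ 3 genes is
   split into three sub-pathways — P<sub>A</sub>∩P<sub>B</sub>,
   P<sub>A</sub>−(P<sub>A</sub>∩P<sub>B</sub>),
   P<sub>B</sub>−(P<sub>A</sub>∩P<sub>B</sub>) — and parts with ≥ 3 genes
   are re-scored and screened by Bonferroni-corrected Cox p-values
   (adjusted p < 0.01 in **every** cohort; at most 100 kept by combined
   rank).
4. **Risk subtyping.** k-means (k-means++ seeding, 50 restarts) on the
   selected sub-pathway PAS splits the training cohort into G1 (moderate)
   and G2 (aggressive), names anchored to Kaplan–Meier outcome.
5. **Classification & evaluation.** An SVM / AdaBoost / Gaussian naive
   Bayes classifier (10-fold CV grid search) transfers the subtype to new
   cohorts, evaluated by Harrell's C-index, the IPCW Brier score and the
   log-rank test.

A built-in multi-cohort simulator plants a prognostic sub-pathway (with
per-cohort monotone platform distortions) so every stage can be validated
against a known ground truth.

## Worked example

Simulate four cohorts of 300 samples (2 of 20 pathways share 6 genes whose
intersection drives the hazard, log-hazard coefficient 1.5), train on
three cohorts and transfer to the held-out fourth:

```r
library(pascrosstalk)

cfg <- sim_config(n_cohorts = 4, samples_per_cohort = 300, n_genes = 800,
                  n_pathways = 20, pathway_size_range = c(10, 20),
                  overlap_spec = data.frame(a = "P01", b = "P02", shared = 6),
                  log_hazard_coeff = 1.5, seed = 42)
study <- simulate_study(cfg)

res <- run_crosstalk_pipeline(study$cohorts[1:3], study$cohorts[[4]],
                              study$collection, n_top = 20, seed = 42)

head(res$ranking, 3)
#>   pathway_id rank_C1 rank_C2 rank_C3 rank_sum    min_p combined_rank
#> 1 P01              1       1       1        3 1.40e-34             1
#> 2 P02              2       2       2        6 2.11e-25             2
#> 3 P13              3      11       3       17 2.44e- 2             3

res$scores$selected
#> [1] "P01|P02|intersection"

attr(res$labels_train, "group_summary")
#>   group     n median_survival rmean
#> 1 G1      176           12.8  21.7
#> 2 G2      124            1.98  3.44

res$report_test
#> <evaluation_report: n = 300 (211 events), C-index = 0.691,
#>  Brier = 0.178 @ t = 5.04, log-rank p = 2.24e-28>
```

The two planted parent pathways dominate the combined ranking; the
screening keeps exactly the planted intersection sub-pathway
(`P01|P02|intersection`) and discards its non-prognostic unique flanks;
clustering puts the short-survival samples in G2 (median survival 1.98 vs
12.8 time units); and the transferred classifier separates the held-out,
platform-distorted cohort with C-index 0.69 and log-rank p ≈ 10⁻²⁸.
Note that a two-level risk factor caps Harrell's C well below 1 (≈ 0.70
at a hazard ratio of 10), so values near 0.7 indicate strong two-group
separation.

Useful entry points if you bring your own data: `read_cohort()` +
`read_gmt()` to load a cohort and gene-set collection, `compute_pas()`,
`combine_ranks()` / `select_top()`, `decompose_crosstalk()` /
`score_subpathways()`, `cluster_samples()` / `choose_k()`,
`train_classifier()` / `predict_groups()` / `evaluate()`, and `plot_km()`
/ `autoplot()` for figures. See the methods vignette
(`vignettes/pathway-crosstalk-methods.Rmd`) for the statistical details
and design decisions.

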