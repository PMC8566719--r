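---
title: "Pathway-crosstalk survival subtyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-crosstalk survival subtyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascrosstalk)
```

## The problem

Single-gene prognostic signatures for breast cancer transfer poorly across
expression platforms: absolute intensities from RNA-seq and the various
microarray generations are not comparable, and signatures built on them are
sensitive to measurement noise in individual genes. `pascrosstalk`
implements a pathway-level alternative: each sample is scored for the
activity of whole gene sets with a rank-based statistic, survival-relevant
gene sets are screened across several independent cohorts, overlapping
("crosstalking") gene sets are decomposed into sub-pathways so the shared
and unique portions can carry distinct prognostic signal, and the selected
sub-pathway activities drive a two-group risk subtyping whose classifier
can be transferred to cohorts profiled on entirely different platforms.

## The pathway activity score (PAS)

For one gene $g$ in one cohort, samples are split at the within-cohort
median of $g$'s expression: samples strictly above the median vote $+1$,
all others vote $-1$. The PAS of pathway $P$ in sample $s$ is the average
vote over the pathway's measured genes,

$$\mathrm{PAS}(P, s) = \frac{1}{|P \cap M|} \sum_{g \in P \cap M}
v_g(s), \qquad v_g(s) \in \{-1, +1\},$$

where $M$ is the set of genes present in the cohort's expression matrix.
Scores therefore lie in $[-1, +1]$, hitting a bound exactly when every
measured gene agrees.

Three decisions here are deliberately conservative:

* **Median split.** The split statistic only needs to separate "high" from
  "low"; the median gives equal-sized groups and depends only on
  within-cohort ranks, which is what makes a model trained on RNA-seq
  transferable to microarray cohorts. Any strictly increasing per-gene
  transformation — scale, shift, log, platform response curves — leaves
  every vote and hence every score unchanged. This invariance is asserted
  by a 200-case property suite in the tests.
* **Ties vote $-1$.** A sample exactly at the median (and any constant
  gene) votes $-1$. The rule is arbitrary but deterministic; with
  continuous expression values it is almost never exercised.
* **Unmeasured genes are excluded, not zero-filled.** The score is an
  average over measured genes only, and the per-row measured-gene count is
  kept as metadata. A pathway with no measured gene is dropped with a
  message rather than silently scored.

For an even number of samples and no median ties each gene contributes
exactly $n/2$ votes of each sign, so every PAS row sums to zero across
samples — a useful built-in check.

## Cross-cohort screening and the combined rank

Per cohort, each pathway's PAS is regressed on survival with a univariate
Cox proportional-hazards model; the association p-value is the score test,
which is the log-rank test's generalization to a continuous covariate.
Degenerate rows (constant PAS, or a cohort with no observed events) get
the sentinel $p = 1$ with a warning instead of an error, so screening a
large collection never aborts mid-way.

Pathways are then ranked within each cohort (rank 1 = smallest p; ties
broken by pathway id so per-cohort ranks are always a permutation) and
aggregated by the **sum of per-cohort ranks** — marginal-utility ranking in
the style of sure independence screening, applied per cohort and then
combined. Remaining ties are broken by the minimum single-cohort p-value
and finally by id, making the combined order total, reproducible, and
invariant to the input order and to any monotone transformation of the
p-values. The top $n = 100$ pathways are kept by default; a warning is
emitted when $n$ falls below the screening heuristic $N/\log N$ for the
largest cohort of size $N$.

## Crosstalk decomposition

Two pathways $A$, $B$ crosstalk when $|P_A \cap P_B| \ge 3$. Each
crosstalking pair generates three candidate sub-pathways —
$P_A \cap P_B$, $P_A - (P_A \cap P_B)$ and $P_B - (P_A \cap P_B)$ — and
only parts with at least 3 genes are retained, so that a sub-pathway PAS
is never an average over fewer than three votes. The three parts of a pair
are pairwise disjoint and union to $P_A \cup P_B$ (a property test).
Identical gene sets arising from different pairs keep distinct
`"A|B|part"` identifiers: provenance matters downstream, and merging would
silently collapse feature rows.

Sub-pathway PASs are recomputed with the identical scoring rule, Cox
p-values are computed per cohort, and a within-cohort Bonferroni
correction is applied (Benjamini–Hochberg is available as an option). A
sub-pathway is *selected* when its adjusted p-value is below
$\alpha = 0.01$ in **every** supplied cohort; if more than 100 survive,
the 100 with the best combined rank of adjusted p-values are kept. The
order — intersect the per-cohort significance calls first, then cap at
100 — is the only reading consistent with both a fixed feature count and a
per-cohort significance filter.

## Risk subtyping

Samples of the anchor (training) cohort are clustered on the selected
sub-pathway PAS matrix with k-means: k-means++ initialization, 50 seeded
restarts, the best within-cluster sum of squares kept. Features enter
unscaled because PAS rows already share the bounded $[-1, 1]$ scale.
Cluster indices are arbitrary, so group names are **anchored to outcome**:
groups are ordered by Kaplan–Meier median survival (restricted mean when a
median is never reached) and named G1 (moderate) to Gk; with the default
$k = 2$, G2 is always the aggressive, worse-survival group. This makes the
naming invariant to permutations of samples or of k-means' internal
labels.

### Choosing k

`choose_k()` compares candidate cluster numbers by the same three metrics
used for final evaluation — C-index, Brier score, log-rank p — treating
the cluster label as the risk factor. Two safeguards are needed to make
this comparison honest, because the in-sample versions of C-index and
Brier improve mechanically with every additional cluster:

1. metrics are computed **out-of-fold** (5-fold; clusters are fit on the
   training folds, held-out samples are assigned to the nearest centroid,
   and the Cox coefficients come from the training folds), and
2. each metric is scored with the **one-standard-error parsimony rule**:
   the smallest k whose mean out-of-fold value is within one fold
   standard error of the best candidate wins that metric (the same
   convention as `lambda.1se` in penalized regression).

The chosen k wins the majority of the three metrics; remaining ties go to
the smaller k. On data simulated with two survival strata this recovers
$k = 2$ from candidates $\{2, 3, 4\}$ in the large majority of seeds,
which the naive in-sample vote provably cannot do.

## Classification and transfer

A classifier maps sub-pathway PAS to the G1/G2 call so the subtype can be
assigned in cohorts where it was never clustered. Three families are
supported, with hyperparameters chosen by mean 10-fold stratified
cross-validated accuracy over fixed grids, ties to the earlier grid row:

| kind | implementation | grid |
|------|----------------|------|
| `svm` | `e1071::svm` | kernel {linear, rbf} × cost {0.1, 1, 10} |
| `adaboost` | AdaBoost.M1 over depth-1 `rpart` stumps | stumps {50, 100, 200} × learning rate {0.1, 1.0} |
| `gaussian` | Gaussian naive Bayes | variance smoothing {1e-9, 1e-7, 1e-5} |

The AdaBoost loop and the Gaussian naive Bayes (with additive variance
smoothing proportional to the largest feature variance) are implemented in
the package; the SVM and the stump learner come from their standard
packages. Transfer recomputes PAS *within* the target cohort — the median
split is per cohort by construction — and performs no cross-cohort
expression normalization; the monotone-invariance property is exactly the
justification. Prediction refuses feature matrices missing any training
feature rather than imputing, and carries the training G1/G2 semantics
without re-anchoring on the target cohort's survival.

## Evaluation

`evaluate()` treats the group label as the covariate of a Cox model and
reports:

* **Harrell's C-index** of the Cox risk score over comparable pairs
  (`survival::concordance`, higher risk = earlier event). When a training
  reference is supplied, the training model's coefficients and baseline
  are used; otherwise the Cox fit is on the evaluated data. Note that a
  two-level risk factor caps the achievable C-index well below 1 (about
  0.70 at a hazard ratio of 10 with balanced groups), because within-group
  pairs are risk ties.
* **IPCW Brier score** at a horizon, by the standard
  inverse-probability-of-censoring-weighted formula with the censoring
  distribution estimated by a Kaplan–Meier on the censoring indicator
  (left-continuous at event times). The horizon defaults to the median
  observed follow-up of the evaluated samples and is reported in every
  report, since no single horizon is canonical.
* **Log-rank p** between the groups (`survival::survdiff`).

A report with only one group present is returned as *partial* (C-index and
log-rank undefined) rather than failing, so cohort-by-cohort loops keep
running.

## The simulator

`sim_config()` / `simulate_study()` generate the structure every stage is
tested against:

* a gene-set collection with controlled pairwise overlaps (listed pairs
  share exactly their specified gene count, unlisted pairs are disjoint);
* one planted effect: a latent activity $a \sim N(0,1)$ per sample shifts
  the mean of the planted sub-pathway's genes (default: the intersection
  of the first overlapping pair), all other genes are independent
  standard-normal noise;
* exponential survival with hazard
  $h_0 \exp(\beta a)$ and an independent exponential censoring time whose
  rate is solved (on the realized hazards) so the expected censoring
  fraction matches `censor_rate`; the observed fraction lands within a few
  percentage points at cohorts of 300+;
* a strictly increasing per-cohort distortion
  $x \mapsto s_1 x + s_2\,\mathrm{sign}(x)|x|^{1/3} + c$ with cohort-specific
  positive $s_1, s_2$, mimicking platform differences while provably
  preserving within-cohort ranks — the property the PAS relies on.

Defaults are 4 cohorts × 300 samples, 2000 genes, 50 pathways of 10–30
genes, one pair sharing 6 genes, $\beta = 1.5$, 30 % censoring: cohort
sizes and effect scale typical of multi-cohort breast-cancer prognosis
studies, and strong enough that the planted intersection is recoverable
while its flanking unique parts are not prognostic.

What the simulator does **not** emulate: realistic expression covariance,
molecular subtype structure, probe-level artifacts, non-proportional
hazards, or batch effects that break ranks. Passing tests therefore show
the pipeline recovers planted signal under its own assumptions, not that
it will reproduce any particular clinical result.

## Problem sizes used by the test suite

The packaged tests run scaled-down but structurally faithful versions of
the study conditions, chosen to keep the default suite inside a few
minutes on one core: property suites use 200 randomized small matrices;
type-I calibration uses 200 null cohorts of 200 samples; family-wise-error
control uses 20 seeds × 2 cohorts × ~200 sub-pathways; recovery and
end-to-end transfer use 20 seeds × (3 training + 1 held-out) cohorts of
300 samples with 800 genes and 20 pathways. `scripts/acceptance.R` runs
the full default conditions (2000 genes, 50 pathways) once per seed.

## Degenerate inputs and numerical choices

* Constant genes vote $-1$ everywhere; constant PAS rows and event-free
  cohorts get sentinel $p = 1$ with a classed warning.
* Gene rows with any missing value are dropped at cohort construction
  (the median split is undefined on missing data); drop counts are
  reported.
* Survival times are never unit-converted; cohorts analysed together must
  share units.
* k-means restarts that produce an empty cluster are discarded; if all 50
  fail, a classed error is raised.
* Cross-validation folds are stratified by class and re-seeded up to 20
  times if a fold loses a class; persistent failure is an error, never a
  silent unstratified fall-back.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so identical calls are bit-identical and never perturb the caller's RNG
  state.

## Known limitations

* The PAS discards within-half magnitude information by design; gains in
  transferability are paid for in per-gene efficiency.
* Bonferroni across hundreds of correlated sub-pathways is conservative;
  the BH option trades family-wise control for power.
* The two-level risk score bounds the reportable C-index (see above);
  comparisons across papers should keep the predictor granularity in
  mind.
* Sub-pathway decomposition is pairwise; higher-order overlaps among three
  or more pathways are represented only through their pairwise parts.
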