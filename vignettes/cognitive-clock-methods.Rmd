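---
title: "Cognitive clocks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive clocks: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogclock)
```

## The problem

Cognitive performance declines with age, but people of the same
chronological age differ widely in how far that decline has progressed. A
*cognitive clock* makes this quantitative: a regression model predicts an
age variable (chronological age, or a biological age such as PhenoAge or a
DNA-methylation age) from summary statistics of cognitive test results, and
the deviation of the predicted age from the age expected for that person —
the *age acceleration* — becomes a per-person biomarker of accelerated or
delayed cognitive aging. `cogclock` implements the whole chain:

1. **Quantifiers** — each cognitive index series (e.g. campimetry stimulus
   recognition time CM t+, motor reaction time SM2 MR) is summarized into
   named statistics (mean, min, max, SD, median, Q1, Q3), giving a fixed
   vector of *cognitive quantifiers* per participant.
2. **Screening** — quantifiers are tested for Pearson correlation with the
   target age (t-distributed null, two-sided), with Benjamini–Hochberg
   control and an adjusted-p threshold of 0.001.
3. **Clock construction** — grid search over model family (linear, elastic
   net, RBF-kernel ε- and ν-SVR, random forest, kNN, Theil–Sen),
   hyperparameters and the number of top-ranked quantifiers, evaluated by
   age-stratified 5-fold cross-validation with the mean explained variance
   (EV) as objective and MAE/MedAE reported alongside.
4. **Acceleration** — per-participant accelerations for the cognitive clock
   and any supplied biological clocks, and their pairwise correlations.
5. **Phenotyping** — each participant's performance is coded
   better/normal/worse relative to Gaussian age-weighted peer statistics,
   the ternary patterns are clustered by K-means, and each cluster's mean
   cognitive acceleration is tested against zero.

Because the underlying human data sets of this kind are typically
restricted, the package ships a synthetic-cohort generator with the
statistical structure the analysis assumes, so every stage is testable end
to end.

## The synthetic cohort

A cohort is generated from a seeded configuration
(`cohort_config()`); defaults describe a 118-participant cohort aged 19–85
(ages uniform, about two-thirds female). Three per-participant latent
variables drive everything:

* **Chronological age** `a` — uniform on the configured range.
* **Latent acceleration** `u ~ N(0, accel_sd²)`, default SD 5 years: how far
  ahead of (or behind) calendar time this person's aging has run. It shifts
  every cognitive index *and* loads on every simulated biological clock.
* **Latent trait** `v ~ N(0, trait_sd²)`, default SD 12 years-equivalent: a
  stable, age-independent performance level, shared across indices but
  invisible to biological clocks. This is what makes age prediction from
  cognitive data genuinely hard — two 50-year-olds with identical aging
  rates still perform differently — and without it a simulated clock is
  implausibly accurate (cross-validated EV above 0.9, MAE under 2 years,
  which no cognitive battery achieves).

Each index has an *effective age* `a + u + v`. Time- and count-valued
indices drift linearly from a baseline at the reference age of 20
(optionally saturating beyond a configurable age, which injects the
nonlinearity that kernel and neighbour models exploit); trial noise is
Gaussian with an optional minority "slow mode" producing the broad, often
bimodal trial distributions seen in reaction-time data. Error/accuracy
fractions are Binomial(`n_trials`, p)/`n_trials` with p logistic in
effective age, so they stay in [0, 1]. Only five of the sixteen default
indices are strongly age-sensitive (the campimetry times and
first-recognized shade, the arithmetic false-rejection fraction, and the
reversed-letter motor time); the rest drift weakly, so screening at a
118-person scale retains roughly 20 of 64 quantifiers rather than all of
them.

Simulated biological ages follow
`intercept + slope·a + loading·u + N(0, σ²)` with per-clock noise chosen so
their agreement with chronological age spans the few-years range typical of
phenotypic and epigenetic clocks. The default shared loading is 0.6.

Ground truth (`u`, `v`, subgroup membership) is written to a separate
`truth.csv` that no analysis stage reads; recovery tests consume it, the
pipeline cannot. Optional subgroups add a fixed shift to `u` for a fraction
of participants, creating "fast/decelerated" or "slow/accelerated"
phenotypes for end-to-end recovery experiments.

What the generator does **not** emulate: stimulus-level psychophysics
(staircase dynamics of the campimetry task), practice and fatigue effects
within a session, sex effects (sex is generated but inert by default),
cohort effects and non-uniform age pyramids, and floor/ceiling artifacts of
real test software. A green recovery test therefore shows the *pipeline*
behaves correctly under the assumed structure, not that real cognitive data
satisfy that structure.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `accel_sd` | 5 | years | Spread of aging acceleration; matches the magnitude of group-level accelerations reported for cognitive phenotypes (≈4–7 y). |
| `trait_sd` | 12 | years-equiv. | Sets the realistic ceiling on clock accuracy (CV MAE ≈ 8–9 y at n = 118). |
| `alpha` | 0.001 | — | BH-adjusted significance threshold for screening. |
| `n_folds` | 5 | — | Cross-validation folds, age-stratified. |
| `age_bins` | 7 equal bins on [10, 90] | years | Stratification labels for fold assignment. |
| `kernel_sd` | 7 | years | Gaussian age window for peer statistics. |
| `threshold_factor` | 0.5 | peer SDs | Better/worse band half-width. |
| `k` | 7 | — | Number of K-means pattern groups. |

## Numerical and procedural choices

* **Quantiles** use linear interpolation between order statistics (R's
  type 7); a single-element series has SD 0 by convention; an empty series
  yields NA for every statistic rather than an error.
* **EV** is the shift-invariant explained-variance form
  `1 − Var(y − ŷ)/Var(y)`; it equals R² when residuals are centered and is
  NA when the target is constant.
* **Stratified folds**: participants are binned by age (out-of-range ages
  clamp to the boundary bins), shuffled within bins, and dealt cyclically
  across the bin-ordered sequence. This guarantees total fold sizes within
  one of each other *and* per-bin counts within one — both properties are
  tested exhaustively.
* **Standardization** (per-quantifier z-scoring) is always fit on the
  training folds only; zero-variance columns are dropped with a log entry.
* **Feature-ranking leakage**: ranking quantifiers on the full data before
  cross-validation (common practice) leaks the held-out fold into the
  ranking. Both modes are provided — `ranking_mode = "pooled"` (rank once;
  default, for comparability with the published practice) and `"strict"`
  (re-rank inside each training fold). A dedicated test verifies that on
  pure-noise cohorts strict mode never outperforms the leaky mode.
* **Objective**: mean CV explained variance by default; mean MAE
  minimization is available as `objective = "mean_MAE"` since both appear
  in the literature for this design. Ties break deterministically by
  smaller top-k, then hyperparameter label, then family name.
* **Theil–Sen with several predictors** is fit sklearn-style: exact
  least-squares on random subsets of p + 1 points, coordinate-wise median
  of the coefficients (all pairwise slopes in the single-predictor case).
* **Acceleration** defaults to the regression-residual form (standard in
  the aging-clock literature: mean-zero, uncorrelated with chronological
  age by construction); the raw difference `clock − chronological` is
  equally supported because group means in years read naturally as
  differences. Correlations across clocks use pairwise-complete rows, so
  clocks measured on a subset of the cohort (as DNA-methylation ages
  usually are) are handled without imputation.
* **Peer statistics**: the Gaussian-weighted SD uses the population
  (Σw-normalized) form without small-sample correction; each participant is
  included in their own reference population (weight 1 at their own age),
  which keeps the moving statistics smooth. The half-SD classification band
  uses strict inequalities, so a value exactly on the boundary is "normal";
  with a zero peer SD any deviation classifies by direction. One SD rather
  than half an SD is a plausible alternative convention; it is exposed as
  `threshold_factor = 1`.
* **K-means** runs on the {−1, 0, +1} encoding with Euclidean distance,
  MacQueen updates (better behaved than Hartigan–Wong on heavily duplicated
  ternary rows), best of 50 restarts. Groups are relabeled A, B, … by
  descending mean count of "better" cells, making letters deterministic and
  ordered from best- to worst-performing.
* **Determinism**: every stochastic step draws from a seed derived from the
  single pipeline seed via fixed offsets; RNG state is saved and restored
  around internal draws, so library code never perturbs a caller's stream.
  A rerun of `run_pipeline()` with the same config reproduces every CSV
  byte-for-byte.

## Problem sizes used in the test suite

The suite exercises the pipeline at the cohort scale the analysis targets
(118 participants, 64 quantifiers) and uses larger simulated cohorts where
a property needs statistical resolution: 1,000 random instances per
statistic for oracle equivalence; 200 null replicates for false-discovery
control; 100 random cohorts for fold balance; n = 500 for linear-signal
recovery with permuted-age negative controls across all seven families;
20 seeds for the nonlinearity comparison (saturating signal, paired sign
test) and for the acceleration-coupling monotonicity in the shared loading
{0, 0.4, 0.8}; 25 seeds for end-to-end recovery of injected
fast/decelerated and slow/accelerated subgroups. Recovery experiments pin
`trait_sd = 0` so that the latent being recovered is the only
participant-level signal; the showcase defaults keep the trait active.

## Known limitations

* The exact composition of a real battery's quantifier list is
  study-specific; the shipped default (7 statistics × 8 series indices + 8
  scalar indices = 64) is a stand-in, and the mapping is configurable data.
* The clock does not adjust for covariates (sex, education) and implements
  no survival-type components.
* K is user-set for the pattern clustering; the package deliberately does
  not choose it by gap statistic or silhouette.
* Biological ages are consumed (or simulated) as columns; computing
  epigenetic or phenotypic ages from raw laboratory data is out of scope.

## A minimal run

```{r, eval = FALSE}
cfg <- default_pipeline_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "cogclock-run")
res$cluster_report
```
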