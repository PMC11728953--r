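---
title: "Predicting rapid decline of kidney function from longitudinal laboratory data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting rapid decline of kidney function from longitudinal laboratory data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A minority of type-2 diabetes patients experience *rapid decline* (RD): a
sudden, steep loss of kidney function visible as a drop in the estimated
glomerular filtration rate (eGFR, mL/min/1.73m²). RD often occurs without
the albuminuria changes that usually announce diabetic kidney disease, so it
is easy to miss in routine care. `rdkidney` implements a complete,
reusable pipeline that (1) labels RD on smoothed eGFR trajectories, (2)
turns labeled histories into prediction instances, (3) engineers
time-resolved features from hundreds of routine laboratory tests, (4) trains
a gradient-boosted tree classifier with recursive feature elimination, and
(5) evaluates it with patient-level holdout and bootstrap confidence
intervals. Because real hospital EHR extracts cannot be redistributed, the
package ships a synthetic-EHR generator with known ground truth; every stage
of the pipeline is exercised and tested against it.

## The RD label

At every date a patient measures eGFR (an *indication point*) the trajectory
is smoothed with LOWESS — locally weighted linear regression with tricube
weights and robustifying iterations — and the date is labeled RD when

* the smoothed eGFR is below 60 mL/min/1.73m² (established kidney disease), and
* the smoothed value has fallen by at least 5 mL/min/1.73m² relative to the
  smoothed curve 365 days earlier.

Design choices that the label definition leaves open, and how this package
resolves them:

* **Smoother span.** The LOWESS fraction is not dictated by the criterion;
  the default is 0.5 with 3 robustifying iterations — wide enough to damp
  visit-frequency artefacts and isolated outliers, while preserving the
  slope change of a genuine episode. Both are configurable
  (`rd_criteria()`).
* **"One year ago"** is operationalized as *linear interpolation of the
  smoothed curve* at `t − 365` days. Using the nearest raw measurement
  instead would re-introduce exactly the visit-timing bias smoothing is
  meant to remove. When no observation exists at or before `t − 365`, the
  reference is undefined and the date cannot be RD (no extrapolation).
* **The level criterion is evaluated on the smoothed value**, consistent
  with smoothing being applied before the criterion; a raw-value option
  exists (`use_smoothed = FALSE`).
* **Series with fewer than 3 points** bypass smoothing (locally weighted
  regression is degenerate there) but are still classified on raw values:
  the labeling policy deliberately sets no minimum test count, so that no
  potential case is screened out.
* **Reason codes** are assigned in the order `above_threshold` →
  `insufficient_lookback` → `drop_too_small`; the value criterion is
  reported first because it is the criterion's leading clause and does not
  depend on history.

The test suite checks the classifier against an independent brute-force
evaluation of the criterion. Because the criterion is *defined on the
smoothed curve*, the oracle takes the smoothed values as given and
re-implements only the reference interpolation and threshold logic; the
smoother itself is validated separately by its exactness on straight lines
and its robustness to planted outliers.

## Decision points and labels

A *decision point* is an eGFR test date at which a prediction is made: will
an RD indication occur within the following 365 days (the *event window*)?
Candidates are all eGFR test dates in the decision period; a candidate is
excluded when a dialysis or transplant event occurred strictly before it,
when it falls on or after the patient's first RD indication (prediction
stops once RD has arrived), or when no later eGFR test exists inside the
event window (the label would be unverifiable). Multiple decision points per
patient are kept deliberately — that is how physicians actually encounter
patients, and it enlarges the training data.

Two window conventions coexist on purpose: "one year" is 365 days for the
event window and the labeling lookback, but the *input window* supplying
features is 54 weeks = 378 days, exactly as specified by the feature scheme.
The package preserves this asymmetry rather than "fixing" it.

## Space features

Within the 378-day input window before each decision point, each laboratory
test is processed as follows, in this order:

1. **Nearest-neighbour daily interpolation** between the earliest and latest
   observation in the window (no extrapolation; equidistant ties resolve to
   the more recent observation, the clinically salient side, and keep the
   output deterministic).
2. **Quantization into 27 fortnight "spaces"**; day offsets 0–13 before the
   decision date form the 1st space, 14–27 the 2nd, and so on.
3. **Representative value** = natural log of the mean of the non-missing
   daily values in the space; an empty space, or a non-positive mean, stays
   missing. Values are never shifted to make logs defined — shifting would
   silently distort every test's scale.

The decision date itself is day offset 0 and belongs to the 1st space: the
decision date is by construction an eGFR test date, and discarding the
triggering measurement would throw away the most recent information.
Missingness is passed through untouched; the learner routes missing values
natively and treats them as informative (patients with RD are *tested*
differently, not just *measured* differently). Each test therefore
contributes exactly 27 features named `1st_space_of_<code>` …
`27th_space_of_<code>`; 1202 test codes give 32,454 columns.

The per-decision-point inner loop is implemented in C++ for speed; the pure
R composition `interpolate_daily()` + `quantize_spaces()` is exported and
the compiled path is tested for exact agreement with it.

## Model and feature selection

The classifier is a leaf-wise gradient-boosted tree ensemble (xgboost with
`grow_policy = "lossguide"`), the natural R counterpart of the LightGBM
family of learners: leaf-wise growth, native missing-value routing, and
native PR-AUC evaluation. Fixed regime: learning rate 0.05, maximum depth
10, 50 leaves, minimum 100 samples per leaf (mapped to a hessian bound of
25, since the logistic-loss hessian is at most 1/4), up to 1000 rounds with
early stopping after 50 rounds without PR-AUC improvement on a validation
split held out by patient (20% of training patients), decision threshold
0.5, gain importance. Five parameters are tunable — `bagging_fraction`,
`bagging_freq`, `feature_fraction`, `lambda_l1`, `lambda_l2` — via a seeded
random search (`tune_hyperparameters()`, default 100 trials) maximizing
mean PR-AUC over 5-fold patient-grouped, label-stratified cross-validation.
`bagging_freq` acts as an on/off gate for row subsampling; a per-k-round
bagging cadence has no exact counterpart in this backend.

Recursive feature elimination removes `ceiling(5% × current)` lowest-gain
features per iteration (at least one) while more than 40 remain, then one
per iteration down to a single feature, recording patient-grouped
cross-validated metrics at each size. Ceiling is used for the batch size so
that "5%" always removes 5 from 95 ( `100, 95, 90, …` ), keeping the
schedule faithful to its stated size sequence; a floor rule would drift to
`100, 95, 91, …`. Importance ties break by stable column order, with the
later column deemed less important. The fold count and grouping inside
RFECV and tuning are design choices of this package: 5 folds, grouped by
patient and stratified by the patient-level label, mirroring the holdout
design and preventing within-patient leakage across folds.

No class rebalancing is applied anywhere: up/down-sampling trades imbalance
for overfitting risk, and the evaluation metrics (PR-AUC, F1) already
expose minority-class behaviour.

## Evaluation

Patients — never decision points — are split 70/30 (test size
`ceiling(0.3 n)`), so no patient's rows straddle the split. Six metrics are
computed: ROC-AUC (trapezoidal over thresholds, implemented as the exactly
equivalent tie-corrected rank statistic and cross-checked against an
independent implementation in the tests), PR-AUC (step-wise area, the
average-precision form), and accuracy, recall, precision and F1 at the 0.5
threshold. With single-class labels the AUCs are undefined and returned as
`NA` with a warning while the threshold metrics are still computed — a
deliberate resolution of the tension between "error" and "still returned".

Confidence intervals come from resampling test-set *decision points* with
replacement 1000 times and taking percentile 2.5/97.5 bounds. The
percentile interval (rather than BCa) is the simplest reproducible choice
for symmetric-looking bounds. Resamples lacking a class are redrawn and
counted, since the AUCs need both classes. Decision points within a patient
are correlated, so the bootstrap unit is a config-level choice one could
revisit; the default follows the resample-the-test-set convention.

Variance inflation factors (`vif()`) are computed on complete cases as
`1/(1 − R²)` from least-squares regressions of each selected feature on the
others; VIF > 10 flags strong multicollinearity. The characteristics table
reports mean (SD) by outcome with Mann-Whitney U p-values, and missingness
and configured bins with Fisher exact p-values (2×2 tables are always
exact; 2×k tables use the exact network algorithm when small — at most 5
bins and 2000 observations — falling back to chi-square with a warning
otherwise). No
multiple-testing correction is applied, matching the table's descriptive
purpose.

## The synthetic generator

`generate_cohort()` emulates the structural features of a hospital EHR
extract that the pipeline depends on, with known ground truth:

* **Visits** follow a homogeneous Poisson process (default 8/patient-year),
  giving irregular spacing. At this rate and the default 30% per-test
  missingness, eligible eGFR-test density matches a realistic diabetes
  outpatient cadence of roughly 13 decision points per patient over the
  2.7-year decision period.
* **eGFR trajectories** are piecewise linear: baseline (mean 75, SD 15)
  with a slow slope (−1/year) switching to a rapid slope (−10/year,
  necessarily ≤ −5) at a planted episode start in 30% of patients, plus
  i.i.d. Gaussian noise (SD 3) truncated so recorded values stay ≥ 1.
  Episode starts are uniform inside the study window with a 90-day margin.
* **Creatinine** is derived from the recorded (noisy) eGFR by exactly
  inverting the Japanese Society of Nephrology 3-variable equation
  `eGFR = 194 · Cr^−1.094 · age^−0.287 (× 0.739 if female)` — adopted
  because the emulated cohort is Japanese; the labeling criterion itself
  only needs a monotone creatinine–eGFR link, but values reported as
  "eGFR" depend on this choice.
* **Informative lab tests** (3 of 50 codes by default) shift upward on the
  log scale as an episode approaches — a linear ramp over the preceding
  year, sustained afterwards (0.5 log units at onset) — so *when* a test
  was measured matters, and the feature-timing machinery ("which space")
  is genuinely exercised. All other codes are lognormal noise, independent
  of ground truth.
* **Dialysis** begins at the first visit where the noise-free eGFR falls
  below 10; no labs are generated after that date. Transplant censoring is
  handled by the cohort logic but not simulated (the `transplant_date`
  column exists and stays `NA`); the exclusion rule is exercised with
  hand-built fixtures in the tests.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: informative missingness (here tests go missing at
random), measurement-batch effects and laboratory drift, comorbidity
structure among the noise tests, medication effects on trajectories, and
the non-random visit intensification that follows clinical deterioration.
Results on the generator validate the *machinery* (no leakage, correct
windows, recoverable signal), not clinical performance.

## Numerical choices and degenerate inputs

* Identical configuration and seed reproduce byte-identical tables and
  reports; every stochastic step (generation, splits, validation holdout,
  tuning draws, bootstrap, and the learner's own column subsampling, which
  draws from R's RNG) is explicitly seeded, and library calls restore the
  caller's RNG state.
* The learner runs single-threaded by default so results do not depend on
  thread scheduling.
* Interpolation ties (a day equidistant between two observations) go to the
  more recent observation; importance ties in RFECV break by column order.
* A validation split that ends up single-class silently falls back to
  training without early stopping rather than failing mid-pipeline;
  genuinely single-class training labels are a hard error.
* Feature matrices are persisted as CSV with the missing-value sentinel
  documented in the file header and doubles printed with 17 significant
  digits, so files round-trip bit-exactly.

## Problem sizes used in the checks

The packaged checks run the full pipeline on cohorts of 500 patients and 50
test codes (about 7,000 decision points and 1,350 features) over 20 seeds,
with 300 boosting rounds and early stopping — large enough for the planted
signal to dominate sampling noise while keeping a complete run of the suite
comfortable on a laptop. The elimination-schedule and bootstrap checks use
reduced tree counts and moderate sample sizes for the same reason; the
schedule itself is scale-free and the bootstrap behaviour is governed by
√n, so neither loses generality at these sizes.

## Known limitations

* The RD criterion's clinical validity is assumed, not assessed; the
  package reproduces a study design, it does not validate thresholds.
* LOWESS behaviour at series ends is less stable than in the interior;
  indications very early in a history rely on few points (mitigated, not
  removed, by the lookback requirement).
* The eGFR equation choice affects any quantity labeled "eGFR"; swap in a
  different monotone equation if emulating a non-Japanese cohort.
* A patient-level bootstrap (respecting within-patient correlation) would
  widen intervals relative to the default decision-point bootstrap.
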