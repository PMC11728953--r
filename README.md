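# rdkidney

Predicting **rapid decline (RD) of kidney function** in type-2 diabetes
from longitudinal laboratory data.

A minority of diabetes patients lose kidney function suddenly — faster than
5 mL/min/1.73m² of eGFR per year — often without the albuminuria changes
that usually announce diabetic kidney disease. `rdkidney` implements, as a
tested and reusable R pipeline, a study design for predicting whether RD
will be indicated within the next year from routine laboratory tests:

1. **RD labeling** — every eGFR test date is classified RD/not-RD on the
   LOWESS-smoothed trajectory: RD iff the smoothed eGFR is **< 60
   mL/min/1.73m²** *and* has dropped **≥ 5 mL/min/1.73m²** versus the
   smoothed curve 365 days earlier.
2. **Decision points** — eligible prediction instances: eGFR test dates
   before the patient's first RD indication, not preceded by dialysis or
   transplant, with a verifying eGFR test inside the 1-year event window.
3. **Space features** — per lab test, nearest-neighbour daily interpolation
   inside a 54-week input window (no extrapolation), quantized into 27
   two-week "spaces", each summarized as the log of its mean
   (`1st_space_of_<test>` = the most recent fortnight). Missing cells stay
   missing; 1202 test codes → 32,454 features.
4. **Model** — a leaf-wise gradient-boosted tree ensemble (xgboost,
   `lossguide`) with native missing-value routing: learning rate 0.05,
   depth 10, 50 leaves, early stopping on PR-AUC, plus recursive feature
   elimination (drop the lowest-gain 5% while > 40 features remain, then
   one-by-one to 1) with patient-grouped cross-validation.
5. **Evaluation** — patient-level 70/30 holdout, six metrics (ROC-AUC,
   PR-AUC, accuracy, recall, precision, F1), 1000-resample percentile
   bootstrap CIs, variance inflation factors, and a cohort-characteristics
   table (Mann-Whitney U / Fisher exact).

Because hospital EHR extracts cannot be shipped, the package includes a
**synthetic-EHR generator** (`generate_cohort()`) with irregular Poisson
visit schedules, planted decline episodes with known ground truth,
informative vs. noise lab tests, per-test missingness, and dialysis
censoring. eGFR and creatinine rows are kept mutually consistent through
the Japanese Society of Nephrology 3-variable equation
`eGFR = 194 · Cr^−1.094 · age^−0.287 (× 0.739 if female)`.

See `vignettes/rapid-decline-pipeline.Rmd` for the full methods account.

## Worked example

```r
library(rdkidney)

cfg <- pipeline_config(
  generator = generator_config(n_patients = 200, seed = 42),
  model     = model_params(n_estimators = 300, early_stopping_rounds = 30),
  bootstrap_B = 1000, seed = 42)
run <- run_pipeline(cfg)
run
#> RD pipeline run
#>   decision points: 2800 (4.8% RD), patients: 200
#>   split: 140 train / 60 test patients
#>   test metrics: ROC-AUC 0.956, PR-AUC 0.635, accuracy 0.975, F1 0.412

subset(run$report$bootstrap, metric %in% c("roc_auc", "pr_auc", "accuracy"))
#>     metric estimate boot_mean lower upper
#> 1  roc_auc    0.956     0.956 0.922 0.983
#> 2   pr_auc    0.635     0.644 0.441 0.815
#> 3 accuracy   0.975     0.976 0.964 0.987

run$report$top_features
#> [1] "5th_space_of_eGFR"   "1st_space_of_LAB002" "4th_space_of_LAB002"
#> [4] "2nd_space_of_eGFR"   "6th_space_of_LAB002" "7th_space_of_LAB002"
#> [7] "7th_space_of_LAB003" "9th_space_of_eGFR"
```

Reading the output: 200 synthetic patients yield 2800 eligible decision
points, of which 4.8% see an RD indication within the following year. The
model separates them with a test-set ROC-AUC of 0.956 (bootstrap 95% CI
0.922–0.983) — the planted episodes are recoverable from the engineered
features — and the features the model relies on are recent eGFR spaces and
the generator's informative lab codes (`LAB002`, `LAB003`), i.e. exactly
where the signal was planted. The accompanying VIF table flags the
mutually correlated eGFR spaces (VIF > 10) as expected for lags of one
trajectory.

A thin command-line wrapper exposes each stage on CSV files
(`inst/cli/rd-pipeline.R simulate | label | featurize | train | evaluate |
pipeline`).

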