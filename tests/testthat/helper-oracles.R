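# Independent brute-force evaluation of the rapid-decline criterion, given
# smoothed values: own interpolation and threshold logic, no calls into the
# package's labeling path.
rd_oracle <- function(dates, smoothed, egfr_threshold = 60,
                      drop_threshold = 5, lookback = 365) {
  x <- as.numeric(dates)
  n <- length(x)
  flags <- logical(n)
  for (i in seq_len(n)) {
    target <- x[i] - lookback
    if (x[1] > target) next
    j <- max(which(x <= target))
    ref <- if (x[j] == target) smoothed[j]
    else smoothed[j] + (smoothed[j + 1] - smoothed[j]) *
      (target - x[j]) / (x[j + 1] - x[j])
    flags[i] <- smoothed[i] < egfr_threshold &&
      (ref - smoothed[i]) >= drop_threshold
  }
  flags
}

# Arithmetic trace of the elimination schedule, independent of run_rfecv
expected_rfecv_sizes <- function(n, cutoff = 40) {
  sizes <- n
  while (n > 1) {
    n <- n - if (n > cutoff) max(1, ceiling(0.05 * n)) else 1
    sizes <- c(sizes, n)
  }
  sizes
}

# A noise-free piecewise-linear eGFR series: slope switches at kink_day
piecewise_series <- function(days, baseline, slope1, slope2, kink_day) {
  baseline + slope1 * pmin(days, kink_day) / 365 +
    slope2 * pmax(days - kink_day, 0) / 365
}

# Small cohort used by several tests
tiny_cohort <- function(seed = 1, n_patients = 60, n_tests = 6, ...) {
  generate_cohort(generator_config(n_patients = n_patients, n_tests = n_tests,
                                   informative_tests = "LAB001",
                                   seed = seed, ...))
}

fast_params <- function(...) {
  # tiny fixtures: regularization off so leaf weights are not L1-shrunk to zero
  args <- utils::modifyList(list(n_estimators = 40, early_stopping_rounds = 0,
                                 min_child_samples = 4, lambda_l1 = 0,
                                 lambda_l2 = 0), list(...))
  do.call(model_params, args)
}
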