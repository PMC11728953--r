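#' Criteria for labeling rapid decline on an eGFR trajectory
#'
#' A test date is an RD indication when the LOWESS-smoothed eGFR is below
#' `egfr_threshold` and has dropped by at least `drop_threshold` relative to
#' the smoothed curve one `lookback` earlier.
#'
#' @param egfr_threshold eGFR level criterion, mL/min/1.73m2 (default 60).
#' @param drop_threshold Minimum decrease over the lookback, mL/min/1.73m2
#'   (default 5).
#' @param lookback Lookback horizon in days (default 365).
#' @param lowess_fraction LOWESS smoother span in (0, 1]; wide enough by
#'   default (0.5) to damp visit-frequency artefacts and minor fluctuations.
#' @param lowess_iterations Robustifying iterations (default 3).
#' @param use_smoothed Evaluate the criterion on smoothed values (default);
#'   set `FALSE` to apply it to raw values.
#' @return List of class `rd_criteria`.
#' @export
rd_criteria <- function(egfr_threshold = 60, drop_threshold = 5,
                        lookback = 365, lowess_fraction = 0.5,
                        lowess_iterations = 3, use_smoothed = TRUE) {
  stopifnot(egfr_threshold > 0, drop_threshold > 0, lookback > 0,
            lowess_fraction > 0, lowess_fraction <= 1,
            lowess_iterations >= 0)
  structure(list(egfr_threshold = egfr_threshold,
                 drop_threshold = drop_threshold, lookback = lookback,
                 lowess_fraction = lowess_fraction,
                 lowess_iterations = lowess_iterations,
                 use_smoothed = isTRUE(use_smoothed)),
            class = "rd_criteria")
}

#' LOWESS-smooth an eGFR series at its observed dates
#'
#' Locally weighted linear regression (tricube weights, robustifying
#' iterations) evaluated at each observed date. Series lying exactly on one
#' straight line are returned unchanged; series with fewer than 3 points
#' bypass smoothing.
#'
#' @param dates Strictly increasing `Date` (or numeric day) vector.
#' @param values Positive eGFR values, same length.
#' @param fraction Smoother span in (0, 1].
#' @param iterations Robustifying iterations.
#' @return Numeric vector of smoothed values at the observed dates.
#' @export
smooth_series <- function(dates, values, fraction = 0.5, iterations = 3) {
  n <- length(values)
  stopifnot(n >= 1, length(dates) == n)
  x <- as.numeric(dates)
  if (is.unsorted(x, strictly = TRUE)) stop("dates must be strictly increasing")
  if (n < 3) return(as.numeric(values))
  lowess(x, values, f = fraction, iter = iterations, delta = 0)$y
}

#' Smoothed value one lookback before a test date
#'
#' Linear interpolation of the smoothed curve at `t - lookback` between the
#' two bracketing observed dates; `NA` when no observation exists at or
#' before `t - lookback` (insufficient history — no extrapolation).
#'
#' @param dates Observed dates (strictly increasing).
#' @param smoothed Smoothed values at those dates.
#' @param t The test date.
#' @param lookback Days to look back (default 365).
#' @return Interpolated value, or `NA_real_` when undefined.
#' @export
reference_value <- function(dates, smoothed, t, lookback = 365) {
  x <- as.numeric(dates)
  target <- as.numeric(t) - lookback
  if (!length(x) || min(x) > target) return(NA_real_)
  approx(x, smoothed, xout = target, rule = 1, ties = "ordered")$y
}

#' Classify every eGFR test date of a patient as RD or not
#'
#' Applies the rapid-decline criterion at each observed date: RD iff the
#' smoothed value is below `egfr_threshold` and the drop versus the smoothed
#' curve one lookback earlier is at least `drop_threshold`. Every test date
#' is classified no matter how few eGFR tests exist; dates with insufficient
#' lookback history cannot be RD.
#'
#' @param dates Strictly increasing test dates.
#' @param values Raw eGFR values at those dates.
#' @param criteria An [rd_criteria()] object.
#' @return A `data.frame` with one row per test date: `date`, `egfr`,
#'   `smoothed`, `reference`, `rd_flag`, and a `reason` code
#'   (`above_threshold`, `insufficient_lookback`, `drop_too_small`, `rd`;
#'   checked in that order).
#' @export
classify_indications <- function(dates, values, criteria = rd_criteria()) {
  n <- length(values)
  stopifnot(length(dates) == n)
  if (n == 0L)
    return(data.frame(date = dates, egfr = numeric(0), smoothed = numeric(0),
                      reference = numeric(0), rd_flag = logical(0),
                      reason = character(0)))
  if (any(values <= 0)) stop("eGFR values must be positive")
  sm <- if (criteria$use_smoothed)
    smooth_series(dates, values, criteria$lowess_fraction,
                  criteria$lowess_iterations)
  else as.numeric(values)
  ref <- vapply(seq_len(n), function(i)
    reference_value(dates, sm, dates[i], criteria$lookback), numeric(1))
  below <- sm < criteria$egfr_threshold
  drop_ok <- !is.na(ref) & (ref - sm >= criteria$drop_threshold)
  rd <- below & drop_ok
  reason <- ifelse(!below, "above_threshold",
            ifelse(is.na(ref), "insufficient_lookback",
            ifelse(!drop_ok, "drop_too_small", "rd")))
  data.frame(date = dates, egfr = as.numeric(values), smoothed = sm,
             reference = ref, rd_flag = rd, reason = reason)
}

#' Label every patient's eGFR test dates in a lab table
#'
#' Convenience wrapper: extracts the eGFR series of each patient from a
#' long-format lab table and runs [classify_indications()].
#'
#' @param labs Lab observation table (`patient_id`, `date`, `test_code`,
#'   `value`).
#' @param criteria An [rd_criteria()].
#' @param egfr_code Test code holding eGFR values (default `"eGFR"`).
#' @return A `data.frame` of indication results with a `patient_id` column.
#' @export
classify_cohort <- function(labs, criteria = rd_criteria(),
                            egfr_code = "eGFR") {
  labs <- as.data.table(labs)
  eg <- labs[labs$test_code == egfr_code]
  data.table::setorder(eg, patient_id, date)
  out <- eg[, classify_indications(date, value, criteria), by = "patient_id"]
  as.data.frame(out)
}
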