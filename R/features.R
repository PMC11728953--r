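#' The 2-week space grid over the 54-week input window
#'
#' Day offsets `d = decision_date - observation_date` run from 0 (the
#' decision date itself) to 377. Space `k` (1-indexed) covers
#' `d` in `[14(k-1), 14k - 1]`; the "1st space" is the most recent
#' fortnight.
#'
#' @param n_spaces Number of spaces (default 27).
#' @param space_width Days per space (default 14).
#' @return List of class `space_grid` with `n_spaces`, `space_width` and
#'   `input_window = n_spaces * space_width`.
#' @export
space_grid <- function(n_spaces = 27, space_width = 14) {
  stopifnot(n_spaces > 0, space_width > 0)
  structure(list(n_spaces = as.integer(n_spaces),
                 space_width = as.integer(space_width),
                 input_window = as.integer(n_spaces * space_width)),
            class = "space_grid")
}

#' Nearest-neighbour daily interpolation inside the input window
#'
#' For each day offset between the smallest and largest observed offsets the
#' value of the observation with minimal `|delta d|` is used; equidistant
#' ties resolve to the more recent observation (smaller offset). Days
#' outside the observed span stay missing — no extrapolation.
#'
#' @param d Integer day offsets of the observations (0 = decision date),
#'   strictly increasing, within `[0, window - 1]`.
#' @param values Observation values.
#' @param window Length of the daily output vector (default 378).
#' @return Numeric vector of length `window` indexed by day offset 0 ..
#'   `window - 1`, `NA` where missing.
#' @export
interpolate_daily <- function(d, values, window = 378) {
  stopifnot(length(d) == length(values))
  out <- rep(NA_real_, window)
  if (!length(d)) return(out)
  d <- as.integer(d)
  if (is.unsorted(d, strictly = TRUE)) stop("offsets d must be strictly increasing")
  if (min(d) < 0 || max(d) >= window) stop("offsets outside the input window")
  days <- min(d):max(d)
  if (length(d) == 1L) {
    out[d + 1L] <- values
    return(out)
  }
  mids <- (d[-1] + d[-length(d)]) / 2
  # day strictly greater than a midpoint belongs to the older neighbour;
  # a day exactly on a midpoint keeps the more recent (smaller-offset) one
  idx <- findInterval(days, mids, left.open = TRUE) + 1L
  out[days + 1L] <- values[idx]
  out
}

#' Quantize daily values into per-space log-of-mean representatives
#'
#' For each space the non-missing daily values are averaged and the natural
#' log of the mean taken. Spaces with no non-missing day, or a non-positive
#' mean, are missing.
#'
#' @param daily Numeric vector of length `grid$input_window` (day offsets
#'   0 .. 377), `NA` where missing.
#' @param grid A [space_grid()].
#' @return Numeric vector of `grid$n_spaces` representative values.
#' @export
quantize_spaces <- function(daily, grid = space_grid()) {
  stopifnot(length(daily) == grid$input_window)
  space <- rep(seq_len(grid$n_spaces), each = grid$space_width)
  vapply(seq_len(grid$n_spaces), function(k) {
    v <- daily[space == k]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    m <- mean(v)
    if (m <= 0) NA_real_ else log(m)
  }, numeric(1))
}

ordinal_suffix <- function(n) {
  suff <- rep("th", length(n))
  last2 <- n %% 100
  last1 <- n %% 10
  normal <- !(last2 %in% 11:13)
  suff[normal & last1 == 1] <- "st"
  suff[normal & last1 == 2] <- "nd"
  suff[normal & last1 == 3] <- "rd"
  paste0(n, suff)
}

#' Feature names for one lab test over a space grid
#'
#' Names follow the `"1st_space_of_<TestCode>"` convention, newest to
#' oldest.
#'
#' @param code Test code.
#' @param grid A [space_grid()].
#' @return Character vector of `grid$n_spaces` names.
#' @export
space_feature_names <- function(code, grid = space_grid()) {
  paste0(ordinal_suffix(seq_len(grid$n_spaces)), "_space_of_", code)
}

#' Build the decision-point feature matrix
#'
#' One row per decision point; for each test code, 27 (by default) columns
#' of log-of-mean space representatives computed from nearest-neighbour
#' daily interpolation restricted to the input window. Only observations
#' with day offset in `[0, input_window)` relative to each decision date
#' contribute — data outside the window can never leak in. Missing cells
#' are `NA` and are passed through untouched (the learner handles them).
#'
#' @param decision_points Output of [extract_decision_points()] (needs
#'   `patient_id`, `date`).
#' @param labs Lab observation table (`patient_id`, `date`, `test_code`,
#'   `value`).
#' @param test_codes Codes to featurize, in the desired column-block order.
#'   Every code must occur in `labs`.
#' @param grid A [space_grid()].
#' @return Numeric matrix `nrow(decision_points)` x
#'   `length(test_codes) * grid$n_spaces`, columns named
#'   `"1st_space_of_<code>"`, ..., rows aligned with `decision_points`.
#' @export
build_feature_matrix <- function(decision_points, labs, test_codes,
                                 grid = space_grid()) {
  labs <- as.data.table(labs)
  unknown <- setdiff(test_codes, unique(labs$test_code))
  if (length(unknown))
    stop("unknown test code(s): ", paste(head(unknown, 5), collapse = ", "))
  pats <- sort(unique(c(decision_points$patient_id, labs$patient_id)))
  dp_pat <- match(decision_points$patient_id, pats)
  dp_day <- as.integer(as.numeric(decision_points$date))
  blocks <- lapply(test_codes, function(code) {
    obs <- labs[labs$test_code == code]
    data.table::setorder(obs, patient_id, date)
    m <- space_features_code(
      dp_pat, dp_day,
      match(obs$patient_id, pats), as.integer(as.numeric(obs$date)),
      as.numeric(obs$value), grid$n_spaces, grid$space_width)
    colnames(m) <- space_feature_names(code, grid)
    m
  })
  x <- do.call(cbind, blocks)
  rownames(x) <- paste0(decision_points$patient_id, "@",
                        as.character(decision_points$date))
  x
}

#' Reference implementation of the per-decision-point space features
#'
#' Pure-R composition of [interpolate_daily()] and [quantize_spaces()] for a
#' single decision point and one test code; the compiled fast path used by
#' [build_feature_matrix()] is checked against it in the test suite.
#'
#' @param obs_days,obs_values Observation days (numeric dates) and values of
#'   one test for one patient.
#' @param decision_day Numeric decision date.
#' @param grid A [space_grid()].
#' @return Numeric vector of `grid$n_spaces` representative values.
#' @export
space_features_reference <- function(obs_days, obs_values, decision_day,
                                     grid = space_grid()) {
  d <- decision_day - obs_days
  inwin <- d >= 0 & d < grid$input_window
  d <- d[inwin]; v <- obs_values[inwin]
  o <- order(d)
  quantize_spaces(interpolate_daily(d[o], v[o], grid$input_window), grid)
}
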