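#' Configuration for the synthetic EHR generator
#'
#' Defines the study conditions the generator emulates: a hospital cohort of
#' type-2 diabetes patients visiting irregularly over a multi-year window,
#' measured on many lab tests of which only a handful carry signal about an
#' upcoming rapid-decline (RD) episode.
#'
#' @param n_patients Number of patients (> 0).
#' @param study_start,study_end Calendar bounds of the observation window.
#' @param visit_rate Mean visits per patient-year (homogeneous Poisson
#'   process). Default 8/year gives an eligible eGFR-test density comparable
#'   to a diabetes outpatient clinic.
#' @param n_tests Total number of lab test codes, including the always-present
#'   `"eGFR"` and `"Cre"` codes; the remainder are opaque `"LAB###"` codes.
#' @param informative_tests Codes whose values shift as a planted episode
#'   approaches; all other LAB codes are pure noise. `NULL` (default) uses
#'   the first three LAB codes (fewer when `n_tests` is small).
#' @param rd_fraction Probability a patient receives a planted rapid-decline
#'   episode.
#' @param baseline_egfr_mean,baseline_egfr_sd Baseline eGFR distribution at
#'   study start, mL/min/1.73m2.
#' @param slow_slope,rapid_slope eGFR slopes in mL/min/1.73m2 per year; the
#'   rapid slope applies from the episode start onward and must be <= -5
#'   (the clinical rapid-decline magnitude) and below the slow slope.
#' @param noise_sd Measurement noise on the eGFR scale (i.i.d. Gaussian,
#'   truncated so recorded eGFR stays >= 1).
#' @param missing_rate_per_test Probability a scheduled test is absent at a
#'   visit; scalar, or a named vector keyed by test code.
#' @param dialysis_egfr_threshold When the noise-free eGFR first falls below
#'   this value at a visit, a dialysis event is recorded and no labs are
#'   generated after that date.
#' @param informative_effect Log-scale mean shift of informative tests at the
#'   episode onset (the shift ramps up linearly over the preceding year).
#' @param seed Integer seed; identical `(config, seed)` pairs reproduce
#'   byte-identical tables.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 500,
                             study_start = as.Date("2018-01-01"),
                             study_end = as.Date("2021-08-31"),
                             visit_rate = 8,
                             n_tests = 50,
                             informative_tests = NULL,
                             rd_fraction = 0.3,
                             baseline_egfr_mean = 75,
                             baseline_egfr_sd = 15,
                             slow_slope = -1,
                             rapid_slope = -10,
                             noise_sd = 3,
                             missing_rate_per_test = 0.3,
                             dialysis_egfr_threshold = 10,
                             informative_effect = 0.5,
                             seed = 1L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  if (is.null(informative_tests))
    informative_tests <- sprintf("LAB%03d", seq_len(min(3, n_tests - 2)))
  cfg <- list(
    n_patients = as.integer(n_patients), study_start = study_start,
    study_end = study_end, visit_rate = visit_rate, n_tests = as.integer(n_tests),
    informative_tests = informative_tests, rd_fraction = rd_fraction,
    baseline_egfr_mean = baseline_egfr_mean, baseline_egfr_sd = baseline_egfr_sd,
    slow_slope = slow_slope, rapid_slope = rapid_slope, noise_sd = noise_sd,
    missing_rate_per_test = missing_rate_per_test,
    dialysis_egfr_threshold = dialysis_egfr_threshold,
    informative_effect = informative_effect, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(
    cfg$n_patients > 0,
    cfg$study_start < cfg$study_end,
    cfg$rd_fraction >= 0, cfg$rd_fraction <= 1,
    cfg$visit_rate > 0,
    cfg$n_tests >= 2,
    cfg$noise_sd >= 0,
    cfg$baseline_egfr_sd >= 0)
  if (cfg$rapid_slope >= cfg$slow_slope)
    stop("rapid_slope must be below slow_slope")
  if (cfg$rapid_slope > -5)
    stop("rapid_slope must be <= -5 (rapid decline by construction)")
  codes <- generator_test_codes(cfg)
  if (!all(cfg$informative_tests %in% codes))
    stop("informative_tests must be among the generated test codes")
  invisible(cfg)
}

#' Lab test codes emitted by a generator configuration
#'
#' `"eGFR"` and `"Cre"` first, then opaque `"LAB###"` codes.
#'
#' @param config A [generator_config()].
#' @return Character vector of length `n_tests`.
#' @export
generator_test_codes <- function(config) {
  c("eGFR", "Cre", sprintf("LAB%03d", seq_len(config$n_tests - 2)))
}

#' Simulate one patient's eGFR trajectory at given visit days
#'
#' Noise-free eGFR is piecewise linear in time: `baseline + slope * t/365`
#' until `episode_day`, switching to `rapid_slope` afterwards. Gaussian noise
#' is added and the recorded value truncated below at 1. The first visit at
#' which the noise-free value falls below `dialysis_threshold` triggers a
#' dialysis event; visits after that day are censored.
#'
#' Draws from the caller's RNG stream; seed upstream for reproducibility.
#'
#' @param visit_days Sorted integer day offsets (from study start).
#' @param baseline eGFR at day 0, mL/min/1.73m2.
#' @param slope Pre-episode slope, mL/min/1.73m2 per year.
#' @param episode_day Day the rapid phase begins, or `NA` for no episode.
#' @param rapid_slope Post-episode slope, per year.
#' @param noise_sd Gaussian noise SD on the eGFR scale.
#' @param dialysis_threshold Noise-free eGFR below which dialysis starts.
#' @return List with `egfr` (recorded values), `noise_free`, `keep` (logical,
#'   visit not censored), and `dialysis_day` (`NA` if never reached).
#' @export
simulate_trajectory <- function(visit_days, baseline, slope,
                                episode_day = NA, rapid_slope = NA,
                                noise_sd = 0, dialysis_threshold = 0) {
  if (is.unsorted(visit_days)) stop("visit_days must be sorted")
  t <- as.numeric(visit_days)
  if (is.na(episode_day)) {
    nf <- baseline + slope * t / 365
  } else {
    nf <- baseline + slope * pmin(t, episode_day) / 365 +
      rapid_slope * pmax(t - episode_day, 0) / 365
  }
  egfr <- pmax(nf + rnorm(length(t), 0, noise_sd), 1)
  below <- which(nf < dialysis_threshold)
  dialysis_day <- if (length(below)) visit_days[below[1]] else NA_integer_
  keep <- if (is.na(dialysis_day)) rep(TRUE, length(t)) else visit_days <= dialysis_day
  list(egfr = egfr, noise_free = nf, keep = keep, dialysis_day = dialysis_day)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Produces a patient table, a long-format lab observation table and a
#' ground-truth table. eGFR and creatinine rows are mutually consistent
#' through [egfr_from_creatinine()] (the recorded noisy eGFR is converted
#' back to the creatinine that would have produced it at the patient's age on
#' the test date). Informative LAB tests shift upward on the log scale as a
#' planted episode approaches (`informative_effect` at onset, ramping over
#' the preceding 365 days, sustained afterwards); noise LAB tests are
#' independent of ground truth. No observation is dated after a patient's
#' dialysis date.
#'
#' @param config A [generator_config()].
#' @return List of class `rd_cohort` with elements `patients` (patient_id,
#'   sex, birth_date, dialysis_date, transplant_date), `labs` (patient_id,
#'   date, test_code, value), `ground_truth` (patient_id, rd_planted,
#'   episode_start, slow_slope, rapid_slope, dialysis_date, transplant_date)
#'   and the `config` used.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  cfg <- config
  codes <- generator_test_codes(cfg)
  lab_codes <- setdiff(codes, c("eGFR", "Cre"))
  miss <- missing_rate_for(cfg, codes)
  total_days <- as.integer(cfg$study_end - cfg$study_start)

  with_seed(cfg$seed, {
    pat_list <- vector("list", cfg$n_patients)
    lab_list <- vector("list", cfg$n_patients)
    gt_list <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%05d", i)
      sex <- if (runif(1) < 0.6) "male" else "female"
      age0 <- runif(1, 40, 80)
      birth <- cfg$study_start - round(age0 * 365.25)
      rd <- runif(1) < cfg$rd_fraction
      episode <- if (rd) round(runif(1, 90, total_days - 90)) else NA_integer_
      baseline <- rnorm(1, cfg$baseline_egfr_mean, cfg$baseline_egfr_sd)
      n_visits <- rpois(1, cfg$visit_rate * total_days / 365)
      days <- sort(unique(round(runif(n_visits, 0, total_days))))
      traj <- simulate_trajectory(days, baseline, cfg$slow_slope,
                                  episode_day = episode,
                                  rapid_slope = cfg$rapid_slope,
                                  noise_sd = cfg$noise_sd,
                                  dialysis_threshold = cfg$dialysis_egfr_threshold)
      keep <- traj$keep
      days_k <- days[keep]
      nk <- length(days_k)
      dialysis_date <- if (is.na(traj$dialysis_day)) as.Date(NA)
                       else cfg$study_start + traj$dialysis_day
      pat_list[[i]] <- data.table(
        patient_id = pid, sex = sex, birth_date = birth,
        dialysis_date = dialysis_date, transplant_date = as.Date(NA))
      gt_list[[i]] <- data.table(
        patient_id = pid, rd_planted = rd,
        episode_start = if (rd) cfg$study_start + episode else as.Date(NA),
        slow_slope = cfg$slow_slope,
        rapid_slope = if (rd) cfg$rapid_slope else NA_real_,
        dialysis_date = dialysis_date, transplant_date = as.Date(NA))
      if (nk == 0L) next
      egfr_v <- traj$egfr[keep]
      age_at <- as.numeric(cfg$study_start + days_k - birth) / 365.25
      cre_v <- creatinine_from_egfr(egfr_v, age_at, sex)
      # informative-signal ramp: 0 a year before the episode, 1 at onset and after
      ramp <- if (rd) pmin(pmax(1 - (episode - days_k) / 365, 0), 1) else rep(0, nk)
      n_lab <- length(lab_codes)
      shift <- outer(ramp, cfg$informative_effect *
                       as.numeric(lab_codes %in% cfg$informative_tests))
      lab_vals <- exp(matrix(rnorm(nk * n_lab, log(100), 0.25), nk, n_lab) + shift)
      tab <- data.table(
        patient_id = pid,
        date = rep(cfg$study_start + days_k, times = 2 + n_lab),
        test_code = rep(c("eGFR", "Cre", lab_codes), each = nk),
        value = c(egfr_v, cre_v, as.numeric(lab_vals)))
      present <- runif(nrow(tab)) >= miss[tab$test_code]
      lab_list[[i]] <- tab[present]
    }
    patients <- data.table::rbindlist(pat_list)
    labs <- data.table::rbindlist(lab_list)
    ground_truth <- data.table::rbindlist(gt_list)
  })
  data.table::setkey(labs, patient_id, date, test_code)
  structure(list(patients = patients, labs = labs,
                 ground_truth = ground_truth, config = cfg),
            class = "rd_cohort")
}

missing_rate_for <- function(cfg, codes) {
  m <- cfg$missing_rate_per_test
  if (is.null(names(m))) {
    out <- setNames(rep(m[1], length(codes)), codes)
  } else {
    out <- setNames(rep(0, length(codes)), codes)
    out[intersect(names(m), codes)] <- m[intersect(names(m), codes)]
  }
  out
}

#' @export
print.rd_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d lab rows, %d test codes\n",
              nrow(x$patients), nrow(x$labs),
              length(unique(x$labs$test_code))))
  cat(sprintf("  planted RD episodes: %d (%.1f%%); dialysis events: %d\n",
              sum(x$ground_truth$rd_planted),
              100 * mean(x$ground_truth$rd_planted),
              sum(!is.na(x$ground_truth$dialysis_date))))
  invisible(x)
}
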