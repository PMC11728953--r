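#' Study windows for decision-point construction
#'
#' The input window supplying features is 54 weeks (378 days); the event
#' window in which an RD indication defines a positive label is 365 days.
#' The deliberate 378 vs 365 mismatch follows the study design ("1 year" is
#' 365 days everywhere except the 54-week input window).
#'
#' @param input_window Days of history available to features (default 378).
#' @param event_window Days of follow-up defining the label (default 365).
#' @param decision_start,decision_end First/last admissible decision dates
#'   (`NULL` = derived from the data: all dates, capped so a full event
#'   window fits before the last observed eGFR date).
#' @return List of class `study_windows`.
#' @export
study_windows <- function(input_window = 378, event_window = 365,
                          decision_start = NULL, decision_end = NULL) {
  stopifnot(input_window > 0, event_window > 0)
  structure(list(input_window = input_window, event_window = event_window,
                 decision_start = decision_start, decision_end = decision_end),
            class = "study_windows")
}

#' Extract eligible decision points with event-window labels
#'
#' Candidates are all eGFR test dates inside the decision period. A
#' candidate is excluded when (a) a dialysis or transplant event occurred
#' strictly before the date, (b) the date is on or after the patient's
#' earliest RD indication (predictions cease once RD is indicated), or
#' (c) no other eGFR test date lies within the event window after it.
#' The label is RD iff any RD indication date falls in
#' `(date, date + event_window]`.
#'
#' @param patients Patient table with `patient_id`, `dialysis_date`,
#'   `transplant_date` (dates or `NA`).
#' @param egfr eGFR test table: `patient_id`, `date` (one row per test).
#' @param indications Output of [classify_cohort()] (`patient_id`, `date`,
#'   `rd_flag`).
#' @param windows A [study_windows()].
#' @return `data.frame` of eligible decision points: `patient_id`, `date`,
#'   `label` (logical: RD within the event window), plus the eligibility
#'   trace columns `pass_censor`, `pass_before_rd`, `pass_future_egfr`
#'   (all `TRUE` on returned rows). Attribute `"exclusions"` carries the
#'   per-rule exclusion counts in candidate order.
#' @export
extract_decision_points <- function(patients, egfr, indications,
                                    windows = study_windows()) {
  patients <- as.data.frame(patients)
  egfr <- as.data.frame(egfr)
  indications <- as.data.frame(indications)
  missing_pat <- setdiff(unique(egfr$patient_id), patients$patient_id)
  if (length(missing_pat))
    stop("patients present in eGFR series but absent from patient table: ",
         paste(head(missing_pat, 5), collapse = ", "))

  ev <- windows$event_window
  dstart <- windows$decision_start
  dend <- windows$decision_end
  if (is.null(dend)) dend <- max(egfr$date) - ev
  if (is.null(dstart)) dstart <- min(egfr$date)

  censor <- with(patients, pmin(
    ifelse(is.na(dialysis_date), Inf, as.numeric(dialysis_date)),
    ifelse(is.na(transplant_date), Inf, as.numeric(transplant_date))))
  censor <- setNames(censor, patients$patient_id)

  rd_ind <- indications[indications$rd_flag, c("patient_id", "date")]
  first_rd <- tapply(as.numeric(rd_ind$date), rd_ind$patient_id, min)

  eg <- egfr[order(egfr$patient_id, egfr$date), ]
  res <- lapply(split(eg$date, eg$patient_id), sort)
  out <- vector("list", length(res))
  names(out) <- names(res)
  for (pid in names(res)) {
    d <- res[[pid]]
    dn <- as.numeric(d)
    cand <- d >= dstart & d <= dend
    if (!any(cand)) next
    frd <- if (pid %in% names(first_rd)) first_rd[[pid]] else Inf
    rd_dates <- as.numeric(rd_ind$date[rd_ind$patient_id == pid])
    pass_censor <- censor[[pid]] >= dn          # exclude only strictly-before events
    pass_before_rd <- dn < frd
    # another eGFR test strictly after the date, within the event window
    pass_future <- vapply(seq_along(dn), function(i)
      any(dn > dn[i] & dn <= dn[i] + ev), logical(1))
    label <- vapply(dn, function(t)
      any(rd_dates > t & rd_dates <= t + ev), logical(1))
    keep <- cand
    out[[pid]] <- data.frame(
      patient_id = pid, date = d[keep], label = label[keep],
      pass_censor = pass_censor[keep], pass_before_rd = pass_before_rd[keep],
      pass_future_egfr = pass_future[keep])
  }
  all_cand <- do.call(rbind, out)
  if (is.null(all_cand))
    all_cand <- data.frame(patient_id = character(0), date = as.Date(character(0)),
                           label = logical(0), pass_censor = logical(0),
                           pass_before_rd = logical(0), pass_future_egfr = logical(0))
  excl <- c(
    candidates = nrow(all_cand),
    excluded_censoring = sum(!all_cand$pass_censor),
    excluded_after_rd = sum(all_cand$pass_censor & !all_cand$pass_before_rd),
    excluded_no_future_egfr = sum(all_cand$pass_censor & all_cand$pass_before_rd &
                                    !all_cand$pass_future_egfr))
  eligible <- all_cand[all_cand$pass_censor & all_cand$pass_before_rd &
                         all_cand$pass_future_egfr, , drop = FALSE]
  rownames(eligible) <- NULL
  excl <- c(excl, eligible = nrow(eligible))
  attr(eligible, "exclusions") <- excl
  eligible
}
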