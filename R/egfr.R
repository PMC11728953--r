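#' Estimated GFR from serum creatinine
#'
#' Japanese Society of Nephrology 3-variable equation for adults:
#' eGFR = 194 * Cr^-1.094 * age^-0.287, multiplied by 0.739 for women.
#' Units: creatinine in mg/dL, age in years, eGFR in mL/min/1.73m2.
#'
#' @param creatinine Serum creatinine, mg/dL. Must be positive.
#' @param age Age in years, >= 18.
#' @param sex `"male"` or `"female"` (recycled against the other arguments).
#' @return eGFR in mL/min/1.73m2; strictly decreasing in both creatinine and
#'   age.
#' @seealso [creatinine_from_egfr()] for the exact inverse.
#' @examples
#' egfr_from_creatinine(1.0, 50, "male")
#' @export
egfr_from_creatinine <- function(creatinine, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(creatinine)) || any(creatinine <= 0))
    stop("creatinine must be positive and finite")
  if (any(age < 18)) stop("equation is for adults (age >= 18)")
  194 * creatinine^-1.094 * age^-0.287 * ifelse(sex == "female", 0.739, 1)
}

#' Serum creatinine implied by an eGFR value
#'
#' Exact inverse of [egfr_from_creatinine()]; used by the synthetic generator
#' to keep creatinine and eGFR rows mutually consistent.
#'
#' @param egfr eGFR in mL/min/1.73m2, positive.
#' @inheritParams egfr_from_creatinine
#' @return Serum creatinine, mg/dL.
#' @export
creatinine_from_egfr <- function(egfr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(egfr)) || any(egfr <= 0))
    stop("egfr must be positive and finite")
  if (any(age < 18)) stop("equation is for adults (age >= 18)")
  base <- 194 * age^-0.287 * ifelse(sex == "female", 0.739, 1)
  (egfr / base)^(-1 / 1.094)
}

match_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be \"male\" or \"female\"")
  sex
}
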