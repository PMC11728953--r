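#' Read a long-format lab observation table
#'
#' Expects a CSV with header `patient_id, date, test_code, value`; dates are
#' ISO-8601. Rows whose value or date fails to parse are rejected and the
#' rejection count reported via a message (and the `"n_rejected"`
#' attribute).
#'
#' @param path CSV path.
#' @return `data.frame` with parsed `date` (`Date`) and numeric `value`.
#' @export
read_lab_table <- function(path) {
  dt <- fread(path, colClasses = list(character = c("patient_id", "test_code")),
              showProgress = FALSE)
  require_columns(dt, c("patient_id", "date", "test_code", "value"), path)
  date <- as.Date(as.character(dt$date), format = "%Y-%m-%d")
  value <- suppressWarnings(as.numeric(dt$value))
  bad <- is.na(date) | is.na(value)
  if (any(bad)) message(sum(bad), " lab row(s) rejected (unparseable date or value)")
  out <- data.frame(patient_id = dt$patient_id[!bad], date = date[!bad],
                    test_code = dt$test_code[!bad], value = value[!bad])
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Read a patient table
#'
#' Expects `patient_id, sex, birth_date, dialysis_date, transplant_date`;
#' empty event dates parse to `NA`.
#'
#' @param path CSV path.
#' @return `data.frame` with `Date` columns.
#' @export
read_patient_table <- function(path) {
  dt <- fread(path, colClasses = "character", showProgress = FALSE)
  require_columns(dt, c("patient_id", "sex", "birth_date",
                        "dialysis_date", "transplant_date"), path)
  parse_d <- function(v) as.Date(ifelse(v == "", NA, v), format = "%Y-%m-%d")
  data.frame(patient_id = dt$patient_id, sex = dt$sex,
             birth_date = parse_d(dt$birth_date),
             dialysis_date = parse_d(dt$dialysis_date),
             transplant_date = parse_d(dt$transplant_date))
}

require_columns <- function(dt, cols, path) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
}

#' Write a table as CSV (lossless doubles, ISO dates)
#'
#' @param x `data.frame`.
#' @param path Output path.
#' @export
write_table_csv <- function(x, path) {
  fwrite(as.data.frame(x), path, dateTimeAs = "ISO")
  invisible(path)
}

#' Write a feature matrix with an explicit missing-value sentinel
#'
#' The file starts with comment lines documenting the missing-value
#' sentinel (`NA`), followed by a CSV whose first column `row_id` holds the
#' decision-point row names. Doubles survive the round trip bit-exactly.
#'
#' @param x Feature matrix from [build_feature_matrix()].
#' @param path Output path.
#' @export
write_feature_matrix <- function(x, path) {
  con <- file(path, "w")
  writeLines(c("# decision-point feature matrix",
               "# missing-value sentinel: NA"), con)
  close(con)
  dt <- data.table(row_id = rownames(x))
  # %.17g guarantees doubles survive the round trip bit-exactly
  chr <- as.data.table(matrix(sprintf("%.17g", x), nrow(x),
                              dimnames = dimnames(x)))
  fwrite(cbind(dt, chr), path, append = TRUE, col.names = TRUE,
         quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input path.
#' @return Numeric matrix with row names restored.
#' @export
read_feature_matrix <- function(path) {
  dt <- fread(path, skip = "row_id", na.strings = "NA", showProgress = FALSE)
  x <- as.matrix(dt[, -1])
  rownames(x) <- dt$row_id
  x
}
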