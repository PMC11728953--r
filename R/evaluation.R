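#' Patient-level 70/30 holdout split
#'
#' Splits patient ids (never decision points) so that no patient's rows
#' straddle the split; the test side receives `ceiling((1 - train_fraction)
#' * n)` patients.
#'
#' @param patient_ids Unique patient identifiers.
#' @param train_fraction Fraction of patients for training (default 0.7).
#' @param seed Seed for the random draw.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_patients <- function(patient_ids, train_fraction = 0.7, seed = 1) {
  if (anyDuplicated(patient_ids)) stop("patient ids must be unique")
  n <- length(patient_ids)
  if (n < 2) stop("need at least 2 patients to split")
  n_test <- ceiling(round((1 - train_fraction) * n, 9))
  test <- with_seed(seed, sample(patient_ids, n_test))
  list(train = setdiff(patient_ids, test), test = test)
}

#' The six classification metrics
#'
#' ROC-AUC by trapezoidal integration over score thresholds (equivalently
#' the tie-corrected rank statistic), PR-AUC as the step-wise area under the
#' precision-recall curve, and accuracy, recall, precision and F1 at the
#' fixed probability threshold.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels (logical or 0/1).
#' @param threshold Decision cutoff (default 0.5; prediction positive when
#'   `score >= threshold`).
#' @return Named list: `roc_auc`, `pr_auc`, `accuracy`, `recall`,
#'   `precision`, `f1`. With single-class labels the AUCs are `NA` with a
#'   warning; the threshold metrics are still returned.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(y), length(y) >= 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class labels: ROC-AUC and PR-AUC are undefined")
    roc <- NA_real_; pr <- NA_real_
  } else {
    r <- rank(scores)
    roc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    pr <- pr_auc_step(scores, y, n1)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (n1 == 0) NA_real_ else tp / n1
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  list(roc_auc = roc, pr_auc = pr, accuracy = mean(pred == y),
       recall = recall, precision = precision, f1 = f1)
}

# area under the PR curve by threshold steps (average-precision form),
# grouping tied scores into a single threshold
pr_auc_step <- function(scores, y, n1) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; yo <- y[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yo); fp <- cumsum(1 - yo)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  rec <- tp / n1
  prec <- tp / (tp + fp)
  sum(diff(c(0, rec)) * prec)
}

#' Bootstrap confidence intervals for the six metrics
#'
#' Resamples decision-point rows of the test set with replacement `B` times
#' (to the original size) and reports, per metric, the point estimate, the
#' bootstrap mean and the `1 - alpha` percentile interval. Resamples lacking
#' a class are redrawn (both AUCs need both classes); the redraw count is
#' attached as attribute `"n_redrawn"`.
#'
#' @param scores,labels Test-set scores and binary labels (both classes
#'   present, at least 2 rows).
#' @param B Bootstrap resamples (default 1000).
#' @param alpha 1 - confidence level (default 0.05).
#' @param seed Seed for the resampling.
#' @param threshold Decision cutoff passed to [compute_metrics()].
#' @return `data.frame` with rows per metric and columns `estimate`,
#'   `boot_mean`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(scores, labels, B = 1000, alpha = 0.05, seed = 1,
                         threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  n <- length(y)
  stopifnot(n >= 2, length(scores) == n)
  if (length(unique(y)) < 2) stop("test labels contain a single class")
  est <- unlist(compute_metrics(scores, y, threshold))
  n_redrawn <- 0L
  boot <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
        n_redrawn <<- n_redrawn + 1L
      }
      unlist(compute_metrics(scores[idx], y[idx], threshold))
    }, numeric(6)))
  })
  qs <- apply(boot, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              na.rm = TRUE, names = FALSE)
  out <- data.frame(metric = names(est), estimate = unname(est),
                    boot_mean = unname(colMeans(boot, na.rm = TRUE)),
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  attr(out, "n_redrawn") <- n_redrawn
  out
}

#' Variance inflation factors of selected features
#'
#' `VIF_j = 1 / (1 - R^2_j)` with `R^2_j` from the least-squares regression
#' of feature `j` on the remaining features plus an intercept. Rows with any
#' missing selected feature are dropped first. A VIF above 10 flags strong
#' multicollinearity.
#'
#' @param x Matrix or data frame of the selected feature columns (>= 1).
#' @return `data.frame` with `feature`, `vif`, and logical `high` (VIF >
#'   10).
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  stopifnot(ncol(x) >= 1)
  cc <- complete.cases(x)
  if (sum(cc) <= ncol(x))
    stop("fewer complete rows than features: VIF is not estimable")
  x <- x[cc, , drop = FALSE]
  v <- vapply(seq_len(ncol(x)), function(j) {
    if (ncol(x) == 1L) return(1)
    fit <- lm(x[[j]] ~ ., data = x[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1))
  data.frame(feature = colnames(x), vif = v, high = v > 10, row.names = NULL)
}

#' Cohort-characteristics table for selected features
#'
#' Summarizes each selected feature by outcome group: mean (SD) with a
#' Mann-Whitney U p-value for the continuous values, and missing counts plus
#' configured bin frequencies with Fisher exact p-values (2 x k tables use
#' the exact network algorithm when small, with a chi-square fallback and a
#' warning otherwise). No multiple-testing correction is applied.
#'
#' @param x Feature matrix or data frame (rows = decision points).
#' @param labels Binary outcome per row (`TRUE` = RD).
#' @param bins Optional named list of numeric break vectors per feature for
#'   the categorical frequency rows.
#' @return `data.frame` with one row per (feature, statistic): columns
#'   `feature`, `statistic`, `rd`, `not_rd`, `p_value`.
#' @export
characteristics_table <- function(x, labels, bins = NULL) {
  x <- as.data.frame(x)
  g <- as.logical(labels)
  stopifnot(nrow(x) == length(g))
  rows <- list()
  for (nm in colnames(x)) {
    v <- x[[nm]]
    miss <- is.na(v)
    p_cont <- if (sum(!miss & g) > 0 && sum(!miss & !g) > 0)
      suppressWarnings(wilcox.test(v[!miss & g], v[!miss & !g])$p.value)
    else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, statistic = "mean (SD)",
      rd = sprintf("%.2f (%.2f)", mean(v[g], na.rm = TRUE),
                   sd(v[g], na.rm = TRUE)),
      not_rd = sprintf("%.2f (%.2f)", mean(v[!g], na.rm = TRUE),
                       sd(v[!g], na.rm = TRUE)),
      p_value = p_cont)
    miss_tab <- rbind(c(sum(miss & g), sum(!miss & g)),
                      c(sum(miss & !g), sum(!miss & !g)))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, statistic = "missing, n (%)",
      rd = sprintf("%d (%.1f)", sum(miss & g), 100 * mean(miss[g])),
      not_rd = sprintf("%d (%.1f)", sum(miss & !g), 100 * mean(miss[!g])),
      p_value = fisher_or_chisq(miss_tab))
    if (!is.null(bins[[nm]])) {
      cut_v <- cut(v, breaks = bins[[nm]], include.lowest = TRUE)
      tab <- table(factor(g, c(TRUE, FALSE)), cut_v)
      p_cat <- fisher_or_chisq(unclass(tab))
      for (lev in colnames(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature = nm, statistic = paste0(lev, ", n (%)"),
          rd = sprintf("%d (%.1f)", tab["TRUE", lev],
                       100 * tab["TRUE", lev] / max(sum(g), 1)),
          not_rd = sprintf("%d (%.1f)", tab["FALSE", lev],
                           100 * tab["FALSE", lev] / max(sum(!g), 1)),
          p_value = p_cat)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exact test when the table is small enough (2x2 is tractable at any size);
# chi-square fallback otherwise
fisher_or_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) < 2) || sum(tab) == 0) return(NA_real_)
  if (ncol(tab) == 2 || (ncol(tab) <= 5 && sum(tab) <= 2000)) {
    p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
    if (!is.na(p)) return(p)
  }
  warning("falling back to chi-square test for a large contingency table")
  suppressWarnings(chisq.test(tab)$p.value)
}
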