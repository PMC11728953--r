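test_that("patient split is an exact, disjoint, seeded partition", {
  ids <- sprintf("P%03d", 1:10)
  sp <- split_patients(ids, 0.7, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_patients(ids, 0.7, seed = 1))
  expect_error(split_patients("P1"), "at least 2")
  expect_error(split_patients(c("P1", "P1", "P2")), "unique")
  for (s in 1:50) {
    spl <- split_patients(sprintf("Q%03d", 1:137), 0.7, seed = s)
    expect_length(intersect(spl$train, spl$test), 0)
    expect_setequal(c(spl$train, spl$test), sprintf("Q%03d", 1:137))
  }
})

test_that("metrics take their closed-form values on constructed cases", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(m), c(roc_auc = 1, pr_auc = 1, accuracy = 1,
                            recall = 1, precision = 1, f1 = 1))
  # all predicted positive on prevalence-p data
  y <- rep(c(1, 0), c(30, 70))
  m2 <- compute_metrics(rep(0.9, 100), y)
  expect_equal(m2$recall, 1)
  expect_equal(m2$precision, 0.3)
  expect_equal(m2$accuracy, 0.3)
})

test_that("independent scores give chance-level ROC-AUC", {
  set.seed(8)
  y <- rep(c(0, 1), each = 5000)
  s <- runif(10000)
  expect_equal(compute_metrics(s, y)$roc_auc, 0.5, tolerance = 0.015 / 0.5)
})

test_that("ROC-AUC matches an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (rep in 1:5) {
    n <- 300
    y <- rbinom(n, 1, 0.3)
    s <- round(plogis(y + rnorm(n)), 2)       # rounded -> plenty of ties
    ours <- compute_metrics(s, y)$roc_auc
    theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                             direction = "<")))
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to row order and flag single-class input", {
  set.seed(10)
  y <- rbinom(200, 1, 0.3)
  s <- runif(200)
  o <- sample(200)
  expect_identical(compute_metrics(s, y), compute_metrics(s[o], y[o]))
  expect_warning(m <- compute_metrics(s, rep(1, 200)), "single-class")
  expect_true(is.na(m$roc_auc) && is.na(m$pr_auc))
  expect_equal(m$accuracy, mean(s >= 0.5))
})

test_that("bootstrap report is seeded, ordered and degenerates correctly at B = 1", {
  set.seed(11)
  y <- rbinom(150, 1, 0.3)
  s <- plogis(2 * y + rnorm(150))
  ci <- bootstrap_ci(s, y, B = 200, seed = 3)
  expect_true(all(ci$lower <= ci$boot_mean + 1e-12 &
                    ci$boot_mean <= ci$upper + 1e-12))
  expect_identical(ci, bootstrap_ci(s, y, B = 200, seed = 3))
  expect_true(all(ci$estimate >= 0 & ci$estimate <= 1))
  one <- bootstrap_ci(s, y, B = 1, seed = 3)
  expect_equal(one$lower, one$boot_mean)
  expect_equal(one$upper, one$boot_mean)
  expect_error(bootstrap_ci(s, rep(1, 150), B = 10), "single class")
  expect_gte(attr(ci, "n_redrawn"), 0)
})

test_that("VIF matches its orthogonality and collinearity limits", {
  set.seed(12)
  x <- matrix(rnorm(20000), 10000, 2, dimnames = list(NULL, c("a", "b")))
  v <- vif(x)
  expect_equal(v$vif, c(1, 1), tolerance = 0.05)
  expect_false(any(v$high))

  dup <- cbind(x, a2 = x[, 1] + rnorm(10000, 0, 1e-4))
  vd <- vif(dup)
  expect_gt(max(vd$vif), 1e4)
  expect_true(vd$high[vd$feature == "a2"])

  expect_equal(vif(x[1:50, 1, drop = FALSE])$vif, 1)
  few <- matrix(rnorm(9), 3, 3)
  few[1, 1] <- NA
  expect_error(vif(few), "complete rows")
})

test_that("characteristics table reproduces the exact Fisher example", {
  # missingness table [[1,9],[11,3]] between RD and not_RD
  g <- rep(c(TRUE, FALSE), c(10, 14))
  v <- c(NA, rnorm(9), rep(NA, 11), rnorm(3))
  tab <- characteristics_table(data.frame(feat = v), g)
  p_miss <- tab$p_value[tab$statistic == "missing, n (%)"]
  expect_equal(p_miss, 0.002759456, tolerance = 1e-6)
})

test_that("group comparisons are calibrated under the null and powered under separation", {
  set.seed(13)
  ps <- replicate(200, {
    tab <- characteristics_table(data.frame(f = rnorm(200)),
                                 rep(c(TRUE, FALSE), each = 100))
    tab$p_value[tab$statistic == "mean (SD)"]
  })
  expect_gte(median(ps), 0.3)
  expect_lte(median(ps), 0.7)

  sep <- characteristics_table(
    data.frame(f = c(rnorm(200, 3), rnorm(200, 0))),
    rep(c(TRUE, FALSE), each = 200))
  expect_lt(sep$p_value[sep$statistic == "mean (SD)"], 1e-10)
})

test_that("binned frequencies appear with a categorical test", {
  set.seed(14)
  v <- c(rnorm(150, 60, 15), rnorm(150, 75, 15))
  g <- rep(c(TRUE, FALSE), each = 150)
  tab <- characteristics_table(data.frame(egfr = v), g,
                               bins = list(egfr = c(-Inf, 45, 60, 90, Inf)))
  expect_equal(sum(grepl("n \\(%\\)", tab$statistic)), 1 + 4)
  p_cat <- tab$p_value[grepl("^\\(", tab$statistic) |
                         grepl("^\\[", tab$statistic)]
  expect_true(all(p_cat == p_cat[1]))
  expect_lt(p_cat[1], 0.01)
})
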