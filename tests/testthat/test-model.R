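sep_fixture <- function(n = 20) {
  x <- cbind(sig = c(seq(0, 0.4, length.out = n / 2),
                     seq(0.6, 1, length.out = n / 2)),
             noise = rep(c(0.2, 0.8), n / 2))
  list(x = x, y = rep(c(0, 1), each = n / 2),
       pid = paste0("P", seq_len(n)))
}

test_that("classifier scores are probabilities and capacity suffices", {
  fx <- sep_fixture()
  fit <- fit_classifier(fx$x, fx$y, fast_params(learning_rate = 0.5))
  s <- predict(fit, fx$x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(mean((s >= 0.5) == fx$y), 1)        # separable -> exact fit
})

test_that("single-class labels and missing columns behave as specified", {
  fx <- sep_fixture()
  expect_error(fit_classifier(fx$x, rep(1, 20), fast_params()),
               "single class")
  x_na <- cbind(fx$x, dead = NA_real_)
  fit <- fit_classifier(x_na, fx$y, fast_params(learning_rate = 0.5))
  expect_equal(unname(importance_gain(fit)["dead"]), 0)
  expect_gt(unname(importance_gain(fit)["sig"]), 0)
})

test_that("early stopping uses a patient-held-out validation split", {
  set.seed(2)
  n <- 400
  pid <- rep(sprintf("P%03d", 1:80), each = 5)
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.7) > 0)
  fit <- fit_classifier(x, y, model_params(n_estimators = 400,
                                           early_stopping_rounds = 20,
                                           min_child_samples = 4),
                        patient_ids = pid, seed = 4)
  expect_lt(fit$best_iteration, 400)
  expect_gt(fit$best_iteration, 0)
})

test_that("patient-grouped folds never split a patient", {
  set.seed(3)
  pid <- sample(sprintf("P%02d", 1:30), 200, replace = TRUE)
  y <- rbinom(200, 1, 0.2)
  folds <- make_patient_folds(pid, y, k = 5, seed = 9)
  expect_true(all(tapply(folds, pid, function(f) length(unique(f))) == 1))
  expect_setequal(unique(folds), 1:5)
  expect_identical(folds, make_patient_folds(pid, y, k = 5, seed = 9))
})

test_that("the elimination schedule follows the 5% batch then one-by-one rule", {
  set.seed(4)
  n <- 150
  x <- matrix(rnorm(n * 100), n, dimnames = list(NULL, paste0("f", 1:100)))
  y <- as.integer(x[, 1] - x[, 2] + rnorm(n) > 0)
  pid <- sprintf("P%03d", seq_len(n))
  sel <- run_rfecv(x, y, pid, fast_params(n_estimators = 8), cv_folds = 0,
                   seed = 1)
  expect_equal(sel$path$n_features, expected_rfecv_sizes(100))
  expect_equal(sel$path$n_features[1:4], c(100, 95, 90, 85))
  sets <- sel$feature_sets
  for (i in seq_along(sets)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))

  small <- run_rfecv(x[, 1:8], y, pid, fast_params(n_estimators = 8),
                     cv_folds = 0, seed = 1)
  expect_equal(small$path$n_features, 8:1)
})

test_that("RFECV keeps informative tests and its metric curve plateaus", {
  co <- generate_cohort(generator_config(n_patients = 120, n_tests = 10,
                                         seed = 41))
  ind <- classify_cohort(co$labs)
  eg <- co$labs[co$labs$test_code == "eGFR", ]
  dp <- extract_decision_points(co$patients, eg, ind,
          study_windows(decision_start = co$config$study_start,
                        decision_end = co$config$study_end - 365))
  x <- build_feature_matrix(dp, co$labs, sort(unique(co$labs$test_code)))
  expect_gt(sum(dp$label), 10)          # the seeded cohort has both classes
  sel <- run_rfecv(x, dp$label, dp$patient_id,
                   model_params(n_estimators = 30, early_stopping_rounds = 0,
                                min_child_samples = 20),
                   cv_folds = 2, seed = 2)
  expect_equal(max(sel$path$n_features), 270)
  ten <- sel$feature_sets[[which(sel$path$n_features == 10)]]
  tests_kept <- unique(sub("^[0-9]+[a-z]+_space_of_", "", ten))
  informative <- c("eGFR", "Cre", co$config$informative_tests)
  expect_gte(length(intersect(tests_kept, informative)), 2)
  auc1 <- sel$path$roc_auc[sel$path$n_features == 1]
  plateau <- max(sel$path$roc_auc[sel$path$n_features >= 5], na.rm = TRUE)
  expect_gt(plateau, auc1)
})

test_that("random-search tuning is seeded and contains the default trial", {
  set.seed(6)
  n <- 240
  pid <- rep(sprintf("P%02d", 1:60), each = 4)
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.5) > 0)
  base <- fast_params(n_estimators = 15)
  one <- tune_hyperparameters(x, y, pid, n_trials = 1, params = base,
                              k = 3, seed = 5)
  expect_equal(one$params$feature_fraction, base$feature_fraction)
  expect_equal(one$params$lambda_l1, base$lambda_l1)

  a <- tune_hyperparameters(x, y, pid, n_trials = 4, params = base,
                            k = 3, seed = 5)
  b <- tune_hyperparameters(x, y, pid, n_trials = 4, params = base,
                            k = 3, seed = 5)
  expect_identical(a$params, b$params)
  expect_gte(a$best_score, a$trials$pr_auc[1])   # default included as trial 1
})
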