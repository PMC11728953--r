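#' Gradient-boosted-tree model parameters
#'
#' The fixed regime: learning rate 0.05, depth 10, 50 leaves (leaf-wise
#' growth), minimum 100 samples per leaf, up to 1000 boosting rounds with
#' early stopping after 50 rounds without PR-AUC improvement on a
#' patient-held-out validation split, decision threshold 0.5, gain
#' importance. Five parameters are tunable: `bagging_fraction`,
#' `bagging_freq`, `feature_fraction`, `lambda_l1`, `lambda_l2`.
#'
#' The backend is xgboost with `grow_policy = "lossguide"` (leaf-wise trees
#' with native missing-value routing). `min_child_samples` maps to
#' `min_child_weight = min_child_samples / 4` because the logistic-loss
#' hessian is bounded by 1/4; `bagging_freq > 0` switches row subsampling on
#' (xgboost has no per-k-round bagging cadence).
#'
#' @param learning_rate Shrinkage (> 0).
#' @param max_depth Maximum tree depth.
#' @param num_leaves Maximum leaves per tree.
#' @param min_child_samples Minimum samples per leaf (hessian-mapped).
#' @param n_estimators Maximum boosting rounds.
#' @param early_stopping_rounds Stop after this many rounds without
#'   validation PR-AUC improvement; 0 disables early stopping.
#' @param threshold Probability cutoff for the binary decision, in (0, 1).
#' @param bagging_fraction,bagging_freq,feature_fraction,lambda_l1,lambda_l2
#'   The five tunable parameters (row subsample fraction and cadence,
#'   column subsample fraction, L1/L2 penalties).
#' @param validation_fraction Fraction of training patients held out for
#'   early stopping.
#' @param nthread Threads used by the learner (default 1; keeps runs
#'   deterministic).
#' @return List of class `model_params`.
#' @export
model_params <- function(learning_rate = 0.05, max_depth = 10,
                         num_leaves = 50, min_child_samples = 100,
                         n_estimators = 1000, early_stopping_rounds = 50,
                         threshold = 0.5, bagging_fraction = 1,
                         bagging_freq = 0, feature_fraction = 0.852,
                         lambda_l1 = 9.998, lambda_l2 = 2.561,
                         validation_fraction = 0.2, nthread = 1) {
  stopifnot(learning_rate > 0, threshold > 0, threshold < 1,
            n_estimators >= 1, bagging_fraction > 0, bagging_fraction <= 1,
            feature_fraction > 0, feature_fraction <= 1,
            lambda_l1 >= 0, lambda_l2 >= 0)
  structure(list(learning_rate = learning_rate, max_depth = max_depth,
                 num_leaves = num_leaves, min_child_samples = min_child_samples,
                 n_estimators = n_estimators,
                 early_stopping_rounds = early_stopping_rounds,
                 threshold = threshold, bagging_fraction = bagging_fraction,
                 bagging_freq = bagging_freq,
                 feature_fraction = feature_fraction,
                 lambda_l1 = lambda_l1, lambda_l2 = lambda_l2,
                 validation_fraction = validation_fraction,
                 nthread = nthread),
            class = "model_params")
}

as_xgb_params <- function(p) {
  list(objective = "binary:logistic", eval_metric = "aucpr",
       eta = p$learning_rate, max_depth = p$max_depth,
       grow_policy = "lossguide", max_leaves = p$num_leaves,
       tree_method = "hist",
       min_child_weight = p$min_child_samples / 4,
       subsample = if (p$bagging_freq > 0) p$bagging_fraction else 1,
       colsample_bytree = p$feature_fraction,
       alpha = p$lambda_l1, lambda = p$lambda_l2,
       nthread = p$nthread)
}

#' Patient-grouped, label-stratified cross-validation folds
#'
#' Assigns whole patients to folds so no patient's decision points straddle
#' a fold boundary; patients are stratified by their patient-level label
#' (any positive decision point).
#'
#' @param patient_ids Patient id per row.
#' @param y Binary labels per row.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer fold id (1..k) per row.
#' @export
make_patient_folds <- function(patient_ids, y, k = 5, seed = 1) {
  pats <- unique(patient_ids)
  pos <- tapply(as.logical(y), patient_ids, any)[pats]
  fold_of <- with_seed(seed, {
    f <- integer(length(pats))
    names(f) <- pats
    for (grp in list(pats[pos], pats[!pos])) {
      grp <- sample(grp)
      f[grp] <- rep_len(seq_len(k), length(grp))
    }
    f
  })
  unname(fold_of[as.character(patient_ids)])
}

#' Fit the gradient-boosted RD classifier
#'
#' Trains a leaf-wise boosted tree ensemble on a feature matrix that may
#' contain missing cells (missingness is routed natively and acts as
#' information). When early stopping is enabled a validation split is held
#' out by patient (or by row when `patient_ids` is `NULL`) and training
#' stops after `early_stopping_rounds` rounds without PR-AUC improvement.
#'
#' @param x Numeric feature matrix (`NA` allowed).
#' @param y Binary labels (logical or 0/1); must contain both classes.
#' @param params A [model_params()].
#' @param patient_ids Optional patient id per row, for the grouped
#'   validation split.
#' @param seed Seed for the validation split.
#' @return Object of class `rd_model` with the fitted booster, feature
#'   names, threshold and best iteration.
#' @export
fit_classifier <- function(x, y, params = model_params(),
                           patient_ids = NULL, seed = 1) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  stopifnot(nrow(x) == length(y))
  xp <- as_xgb_params(params)
  es <- params$early_stopping_rounds
  if (es > 0) {
    idx_val <- validation_rows(y, patient_ids, params$validation_fraction, seed)
    # degenerate single-class split on either side: fall back to no early stop
    if (length(unique(y[idx_val])) < 2 ||
        length(unique(y[-idx_val])) < 2) es <- 0
  }
  # the xgboost R package draws from R's RNG (e.g. column subsampling):
  # seed locally so identical calls yield identical boosters
  if (es > 0) {
    dtr <- xgboost::xgb.DMatrix(x[-idx_val, , drop = FALSE],
                                label = y[-idx_val], missing = NA)
    dva <- xgboost::xgb.DMatrix(x[idx_val, , drop = FALSE],
                                label = y[idx_val], missing = NA)
    booster <- with_seed(seed,
      xgboost::xgb.train(xp, dtr, nrounds = params$n_estimators,
                         evals = list(valid = dva),
                         early_stopping_rounds = es, verbose = 0))
    best <- as.integer(xgboost::xgb.attr(booster, "best_iteration"))
  } else {
    dtr <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
    booster <- with_seed(seed,
      xgboost::xgb.train(xp, dtr, nrounds = params$n_estimators,
                         verbose = 0))
    best <- params$n_estimators
  }
  structure(list(booster = booster, feature_names = colnames(x),
                 threshold = params$threshold, best_iteration = best,
                 params = params),
            class = "rd_model")
}

validation_rows <- function(y, patient_ids, fraction, seed) {
  if (is.null(patient_ids)) {
    return(with_seed(seed, sample(length(y), max(1, round(fraction * length(y))))))
  }
  pats <- unique(patient_ids)
  val_pats <- with_seed(seed, sample(pats, max(1, round(fraction * length(pats)))))
  which(patient_ids %in% val_pats)
}

#' @export
predict.rd_model <- function(object, newdata, ...) {
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  predict(object$booster, xgboost::xgb.DMatrix(newdata, missing = NA))
}

#' @export
print.rd_model <- function(x, ...) {
  cat(sprintf("RD classifier: %d features, best iteration %d, threshold %.2f\n",
              length(x$feature_names), x$best_iteration, x$threshold))
  invisible(x)
}

#' Gain importance of every feature of a fitted model
#'
#' @param model An `rd_model`.
#' @return Named numeric vector over all training features (0 for features
#'   never used in a split), in training column order.
#' @export
importance_gain <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  out[imp$Feature] <- imp$Gain
  out
}

cv_mean_metrics <- function(x, y, patient_ids, params, k = 5, seed = 1) {
  folds <- make_patient_folds(patient_ids, y, k, seed)
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
      return(NULL)
    fit <- fit_classifier(x[tr, , drop = FALSE], y[tr], params,
                          patient_ids = patient_ids[tr], seed = seed + f)
    suppressWarnings(
      compute_metrics(predict(fit, x[!tr, , drop = FALSE]), y[!tr],
                      params$threshold))
  })
  per_fold <- Filter(Negate(is.null), per_fold)
  if (!length(per_fold)) stop("no usable cross-validation fold")
  colMeans(do.call(rbind, lapply(per_fold, unlist)), na.rm = TRUE)
}

#' Tune the five designated hyperparameters
#'
#' Seeded random search maximizing mean PR-AUC over patient-grouped
#' cross-validation folds; the first trial is the default configuration, so
#' the best objective can never fall below the default's.
#'
#' @param x,y,patient_ids Training matrix, labels and patient groups.
#' @param n_trials Number of search trials (including the default trial).
#' @param params Base [model_params()]; only the five tunables vary.
#' @param k Cross-validation folds.
#' @param seed Seed; identical seeds reproduce identical selections.
#' @return List with `params` (best configuration), `best_score` and the
#'   full `trials` data frame.
#' @export
tune_hyperparameters <- function(x, y, patient_ids, n_trials = 100,
                                 params = model_params(), k = 5, seed = 1) {
  stopifnot(n_trials >= 1)
  draws <- with_seed(seed, data.frame(
    bagging_fraction = runif(n_trials, 0.5, 1),
    bagging_freq = sample(0:7, n_trials, replace = TRUE),
    feature_fraction = runif(n_trials, 0.4, 1),
    lambda_l1 = exp(runif(n_trials, log(1e-3), log(10))),
    lambda_l2 = exp(runif(n_trials, log(1e-3), log(10)))))
  draws[1, ] <- c(params$bagging_fraction, params$bagging_freq,
                  params$feature_fraction, params$lambda_l1, params$lambda_l2)
  scores <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    p <- params
    p[names(draws)] <- as.list(draws[i, ])
    scores[i] <- cv_mean_metrics(x, y, patient_ids, p, k, seed)[["pr_auc"]]
  }
  best <- which.max(scores)
  out <- params
  out[names(draws)] <- as.list(draws[best, ])
  list(params = out, best_score = scores[best],
       trials = cbind(draws, pr_auc = scores))
}

#' Recursive feature elimination with cross-validation
#'
#' Iteratively fits the classifier, ranks features by gain importance, and
#' removes the `ceiling(5% * current)` lowest-ranked features (at least 1)
#' while more than 40 remain, thereafter exactly one per iteration down to a
#' single feature. At each size, patient-grouped cross-validated ROC-AUC,
#' PR-AUC, accuracy, recall, precision and F1 are recorded. Importance ties
#' break by stable column order (the later column is considered less
#' important).
#'
#' @param x,y,patient_ids Training matrix, labels and patient groups.
#' @param params A [model_params()].
#' @param cv_folds Folds for the per-size metrics (0 skips metric
#'   recording; the elimination path is unchanged).
#' @param elimination_cutoff Feature count above which the 5% batch rule
#'   applies (default 40).
#' @param seed Seed for folds and validation splits.
#' @return Object of class `selection_path`: a data frame `path` with one
#'   row per size (`n_features` plus the six metrics) and the list
#'   `feature_sets` of retained column names, nested along the path.
#' @export
run_rfecv <- function(x, y, patient_ids, params = model_params(),
                      cv_folds = 5, elimination_cutoff = 40, seed = 1) {
  stopifnot(ncol(x) >= 1)
  feats <- colnames(x)
  if (is.null(feats)) stop("feature matrix must have column names")
  sizes <- integer(0)
  rows <- list()
  sets <- list()
  repeat {
    n <- length(feats)
    sizes <- c(sizes, n)
    sets[[length(sets) + 1L]] <- feats
    xs <- x[, feats, drop = FALSE]
    met <- if (cv_folds >= 2)
      cv_mean_metrics(xs, y, patient_ids, params, cv_folds, seed)
    else
      c(roc_auc = NA_real_, pr_auc = NA_real_, accuracy = NA_real_,
        recall = NA_real_, precision = NA_real_, f1 = NA_real_)
    rows[[length(rows) + 1L]] <- met
    if (n == 1L) break
    fit <- fit_classifier(xs, y, params, patient_ids = patient_ids, seed = seed)
    gain <- importance_gain(fit)
    n_rm <- if (n > elimination_cutoff) max(1L, ceiling(0.05 * n)) else 1L
    # ascending gain; among ties the later column ranks lower and goes first
    drop_idx <- order(gain, -seq_along(gain))[seq_len(n_rm)]
    feats <- feats[-drop_idx]
  }
  path <- data.frame(n_features = sizes,
                     do.call(rbind, rows), row.names = NULL)
  structure(list(path = path, feature_sets = sets), class = "selection_path")
}

#' @export
print.selection_path <- function(x, ...) {
  cat(sprintf("RFECV selection path: %d sizes from %d down to %d features\n",
              nrow(x$path), max(x$path$n_features), min(x$path$n_features)))
  print(head(x$path, 10))
  invisible(x)
}
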