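#' Full-run configuration
#'
#' Gathers every tunable of the pipeline in one place; the resolved
#' configuration is serialized next to the outputs for provenance.
#'
#' @param generator A [generator_config()], or `NULL` when reading tables
#'   from `patient_path`/`lab_path`.
#' @param patient_path,lab_path Optional CSV inputs used instead of the
#'   generator.
#' @param criteria An [rd_criteria()].
#' @param windows A [study_windows()].
#' @param grid A [space_grid()].
#' @param model A [model_params()].
#' @param train_fraction Patient-level holdout fraction for training.
#' @param bootstrap_B,bootstrap_alpha Bootstrap resamples and 1 - confidence
#'   level.
#' @param tune_trials Random-search trials for hyperparameter tuning (0
#'   disables tuning).
#' @param rfecv Run the recursive feature elimination path (logical).
#' @param rfecv_cv_folds Folds for per-size RFECV metrics.
#' @param n_top_features Features (by gain) summarized in the VIF and
#'   characteristics tables.
#' @param seed Global seed; identical seeds reproduce identical reports.
#' @param outdir Output directory (`NULL` = nothing written).
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            patient_path = NULL, lab_path = NULL,
                            criteria = rd_criteria(),
                            windows = study_windows(),
                            grid = space_grid(),
                            model = model_params(),
                            train_fraction = 0.7,
                            bootstrap_B = 1000, bootstrap_alpha = 0.05,
                            tune_trials = 0, rfecv = FALSE,
                            rfecv_cv_folds = 5, n_top_features = 8,
                            seed = 1L, outdir = NULL) {
  structure(list(generator = generator, patient_path = patient_path,
                 lab_path = lab_path, criteria = criteria, windows = windows,
                 grid = grid, model = model, train_fraction = train_fraction,
                 bootstrap_B = bootstrap_B, bootstrap_alpha = bootstrap_alpha,
                 tune_trials = tune_trials, rfecv = rfecv,
                 rfecv_cv_folds = rfecv_cv_folds,
                 n_top_features = n_top_features,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the whole prediction pipeline
#'
#' Orchestrates simulate (or load) -> label -> cohort -> featurize ->
#' split -> (tune) -> train -> evaluate, and writes the report tables to
#' `config$outdir` when set: decision points, feature matrix, metric report
#' with bootstrap CIs, selection path (when RFECV is enabled), VIF table,
#' characteristics table, and the resolved configuration. Identical seeds
#' reproduce identical reports.
#'
#' @param config A [pipeline_config()].
#' @return List of class `rd_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  cohort <- with_stage("simulate", {
    if (!is.null(config$lab_path)) {
      list(patients = read_patient_table(config$patient_path),
           labs = read_lab_table(config$lab_path), ground_truth = NULL)
    } else {
      gen <- config$generator
      gen$seed <- seed
      generate_cohort(gen)
    }
  })

  indications <- with_stage("label",
    classify_cohort(cohort$labs, config$criteria))

  dps <- with_stage("cohort", {
    eg <- cohort$labs[cohort$labs$test_code == "eGFR", ]
    extract_decision_points(cohort$patients, eg, indications, config$windows)
  })

  codes <- sort(unique(cohort$labs$test_code))
  x <- with_stage("featurize",
    build_feature_matrix(dps, cohort$labs, codes, config$grid))
  y <- dps$label

  sp <- with_stage("split",
    split_patients(unique(dps$patient_id), config$train_fraction, seed))
  tr <- dps$patient_id %in% sp$train

  params <- config$model
  if (config$tune_trials > 0) {
    params <- with_stage("tune",
      tune_hyperparameters(x[tr, , drop = FALSE], y[tr], dps$patient_id[tr],
                           n_trials = config$tune_trials, params = params,
                           seed = seed)$params)
  }

  fit <- with_stage("train",
    fit_classifier(x[tr, , drop = FALSE], y[tr], params,
                   patient_ids = dps$patient_id[tr], seed = seed))

  report <- with_stage("evaluate", {
    scores <- predict(fit, x[!tr, , drop = FALSE])
    metrics <- suppressWarnings(compute_metrics(scores, y[!tr], params$threshold))
    ci <- bootstrap_ci(scores, y[!tr], B = config$bootstrap_B,
                       alpha = config$bootstrap_alpha, seed = seed,
                       threshold = params$threshold)
    gain <- sort(importance_gain(fit), decreasing = TRUE)
    top <- names(gain)[gain > 0]
    top <- head(top, config$n_top_features)
    vif_tab <- tryCatch(vif(x[!tr, top, drop = FALSE]),
                        error = function(e) NULL)
    chars <- characteristics_table(x[!tr, top, drop = FALSE], y[!tr])
    sel <- if (isTRUE(config$rfecv))
      run_rfecv(x[tr, , drop = FALSE], y[tr], dps$patient_id[tr], params,
                cv_folds = config$rfecv_cv_folds, seed = seed)
    else NULL
    list(metrics = metrics, bootstrap = ci, top_features = top,
         vif = vif_tab, characteristics = chars, selection = sel,
         scores = scores, test_labels = y[!tr])
  })

  out <- structure(list(
    config = config, decision_points = dps,
    exclusions = attr(dps, "exclusions"), split = sp,
    model = fit, params = params, report = report,
    feature_matrix = x), class = "rd_report")

  if (!is.null(config$outdir)) write_report(out, config$outdir)
  out
}

write_report <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(run$decision_points, file.path(outdir, "decision_points.csv"))
  write_feature_matrix(run$feature_matrix, file.path(outdir, "feature_matrix.csv"))
  write_table_csv(run$report$bootstrap, file.path(outdir, "metric_report.csv"))
  if (!is.null(run$report$vif))
    write_table_csv(run$report$vif, file.path(outdir, "vif_table.csv"))
  write_table_csv(run$report$characteristics,
                  file.path(outdir, "characteristics_table.csv"))
  if (!is.null(run$report$selection))
    write_table_csv(run$report$selection$path,
                    file.path(outdir, "selection_path.csv"))
  yaml::write_yaml(serialize_config(run$config),
                   file.path(outdir, "resolved_config.yaml"))
  invisible(outdir)
}

serialize_config <- function(config) {
  rapply(unclass(config), how = "replace", f = function(v) {
    if (inherits(v, "Date")) as.character(v) else v
  })
}

#' @export
print.rd_report <- function(x, ...) {
  cat("RD pipeline run\n")
  cat(sprintf("  decision points: %d (%.1f%% RD), patients: %d\n",
              nrow(x$decision_points), 100 * mean(x$decision_points$label),
              length(unique(x$decision_points$patient_id))))
  cat(sprintf("  split: %d train / %d test patients\n",
              length(x$split$train), length(x$split$test)))
  m <- x$report$metrics
  cat(sprintf("  test metrics: ROC-AUC %.3f, PR-AUC %.3f, accuracy %.3f, F1 %.3f\n",
              m$roc_auc, m$pr_auc, m$accuracy, m$f1))
  invisible(x)
}
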