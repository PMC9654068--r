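# End-to-end orchestration of the two analyses, with a manifest capturing
# config, seeds and data fingerprints so runs are reproducible.

#' Configuration for an end-to-end run
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (or the
#'   cohort to emulate when ingesting external tables).
#' @param grid_step CGM grid spacing in minutes.
#' @param n_folds Cross-validation folds for RFE and tuning.
#' @param nrounds Boosting rounds.
#' @param do_rfe,do_tune Toggle recursive feature elimination and
#'   hyperparameter search (both on by default; switching them off fits with
#'   default hyperparameters on the full feature set).
#' @param n_random Random-search draws for the regression model.
#' @param mealdetect_activity Append per-interval activity columns to the
#'   CGM meal-detection features (off by default: CGM-only features).
#' @param threshold Classification decision threshold.
#' @param k_top Features tallied per glucose peak.
#' @param min_peaks Minimum peaks for a subject to enter the peak report.
#' @param seed Master seed for modeling stages (the cohort keeps its own).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(), grid_step = 15,
                       n_folds = 10, nrounds = 100, do_rfe = TRUE,
                       do_tune = TRUE, n_random = 20,
                       mealdetect_activity = FALSE, threshold = 0.5,
                       k_top = 5, min_peaks = 10, seed = cohort$seed) {
  structure(list(
    cohort = cohort, grid_step = grid_step, n_folds = n_folds,
    nrounds = nrounds, do_rfe = do_rfe, do_tune = do_tune,
    n_random = n_random, mealdetect_activity = mealdetect_activity,
    threshold = threshold, k_top = k_top, min_peaks = min_peaks,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @noRd
prepare_cohort <- function(config, cohort = NULL) {
  cohort <- cohort %||% inject_gaps(simulate_cohort(config$cohort))
  aligned <- build_aligned_frame(cohort, grid_step = config$grid_step)
  stretches <- select_stretches(aligned, grid_step = config$grid_step)
  if (nrow(stretches) == 0) stopf("no eligible subjects after stretch selection")
  aligned <- add_stretch_ids(aligned, stretches)
  list(cohort = cohort, aligned = aligned, stretches = stretches)
}

#' @noRd
run_manifest <- function(config, stage_seeds, extra) {
  c(list(
    package = "glucolens",
    version = as.character(utils::packageVersion("glucolens")),
    r_version = as.character(getRversion()),
    xgboost_version = as.character(utils::packageVersion("xgboost")),
    config = config[setdiff(names(config), "cohort")],
    cohort_config = unclass(config$cohort),
    seeds = stage_seeds
  ), extra)
}

#' Run the meal-detection analysis end to end
#'
#' Simulates (or accepts) a cohort, aligns it to the CGM grid, selects
#' uninterrupted stretches, splits the first 4 days for training and the
#' next 3 for testing, builds the CGM feature space with 30-min eating
#' labels, optionally runs RFE and grid-search tuning, fits the classifier
#' and reports train/test metrics.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `raw_cohort` (gaps already injected);
#'   by default the config's synthetic cohort is simulated.
#' @return A list of artifacts: `features`, `rfe`, `tuning`, `bundle`,
#'   `metrics` (`$train`, `$test`), `stretches`, `manifest`.
#' @export
run_mealdetect <- function(config = run_config(), cohort = NULL) {
  prep <- prepare_cohort(config, cohort)
  aligned <- split_mealdetect(prep$aligned, grid_step = config$grid_step)
  feats <- build_cgm_features(aligned)
  if (nrow(feats) == 0 || !any(feats$split == "train", na.rm = TRUE))
    stopf("no eligible subjects with training data")
  predictors <- cgm_feature_names()
  if (config$mealdetect_activity) {
    act <- aligned[, c("subject_id", "timestamp", "energy_expenditure",
                       "acceleration", "heart_rate")]
    feats <- dplyr::left_join(feats, act, by = c("subject_id", "timestamp"))
    predictors <- c(predictors, "energy_expenditure", "acceleration",
                    "heart_rate")
  }
  meals <- aggregate_meals(prep$cohort$diary)
  feats$label <- build_meal_labels(feats, meals, grid_step = config$grid_step)

  seeds <- list(rfe = child_seed(config$seed, 11L),
                tune = child_seed(config$seed, 12L),
                fit = child_seed(config$seed, 13L))
  tr <- feats[!is.na(feats$split) & feats$split == "train", , drop = FALSE]
  te <- feats[!is.na(feats$split) & feats$split == "test", , drop = FALSE]

  rfe <- NULL
  selected <- predictors
  if (config$do_rfe) {
    rfe <- rfe_select(tr[, selected], tr$label, "meal_classification",
                      n_folds = config$n_folds, nrounds = config$nrounds,
                      seed = seeds$rfe)
    selected <- rfe$selected_features
  }
  tuning <- NULL
  params <- list()
  if (config$do_tune) {
    tuning <- tune_hyperparams(tr[, selected], tr$label,
                               "meal_classification",
                               n_folds = config$n_folds,
                               nrounds = config$nrounds, seed = seeds$tune)
    params <- tuning$params
  }
  bundle <- fit_model(tr[, selected], tr$label, "meal_classification",
                      params = params, nrounds = config$nrounds,
                      seed = seeds$fit)
  metrics <- lapply(list(train = tr, test = te), function(df) {
    classification_metrics(predict(bundle, df), df$label, df$subject_id,
                           threshold = config$threshold)
  })
  manifest <- run_manifest(config, seeds, list(
    analysis = "meal_detection",
    n_subjects_retained = dplyr::n_distinct(feats$subject_id),
    n_predictors = length(predictors),
    n_selected = length(selected),
    n_rows = list(train = nrow(tr), test = nrow(te)),
    prevalence = list(train = mean(tr$label), test = mean(te$label))
  ))
  list(features = feats, rfe = rfe, tuning = tuning, bundle = bundle,
       metrics = metrics, stretches = prep$stretches, manifest = manifest)
}

#' Run the glucose prediction and explanation analysis end to end
#'
#' Simulates (or accepts) a cohort, builds the 72 rolling predictors plus
#' subject indicators, holds out each subject's last 3 days, optionally runs
#' RFE and random-search tuning, fits the log-glucose regressor, computes
#' exact Shapley attributions on the training rows, detects Q3 + IQR glucose
#' peaks per subject, and reports MAE, Bland-Altman agreement, grouped
#' importance and the per-peak top-k feature frequencies.
#'
#' @inheritParams run_mealdetect
#' @return A list of artifacts: `features`, `rfe`, `tuning`, `bundle`,
#'   `explanation`, `peaks`, `importance`, `peak_frequency`, `metrics`
#'   (`$train`, `$test`, each with `mae` and `bland_altman`), `stretches`,
#'   `manifest`.
#' @export
run_glucose <- function(config = run_config(), cohort = NULL) {
  prep <- prepare_cohort(config, cohort)
  aligned <- split_glucose(prep$aligned, grid_step = config$grid_step)
  feats <- build_glucose_features(aligned, grid_step = config$grid_step)
  if (nrow(feats) == 0 || !any(feats$split == "train", na.rm = TRUE))
    stopf("no eligible subjects with training data")
  predictors <- c(attr(feats, "predictors"), attr(feats, "subject_cols"))

  seeds <- list(rfe = child_seed(config$seed, 21L),
                tune = child_seed(config$seed, 22L),
                fit = child_seed(config$seed, 23L))
  tr <- feats[!is.na(feats$split) & feats$split == "train", , drop = FALSE]
  te <- feats[!is.na(feats$split) & feats$split == "test", , drop = FALSE]

  rfe <- NULL
  selected <- predictors
  if (config$do_rfe) {
    rfe <- rfe_select(tr[, selected], tr$log_glucose, "glucose_regression",
                      n_folds = config$n_folds, nrounds = config$nrounds,
                      seed = seeds$rfe)
    selected <- rfe$selected_features
  }
  tuning <- NULL
  params <- list()
  if (config$do_tune) {
    tuning <- tune_hyperparams(tr[, selected], tr$log_glucose,
                               "glucose_regression",
                               n_folds = config$n_folds,
                               nrounds = config$nrounds, seed = seeds$tune,
                               n_random = config$n_random)
    params <- tuning$params
  }
  bundle <- fit_model(tr[, selected], tr$log_glucose, "glucose_regression",
                      params = params, nrounds = config$nrounds,
                      seed = seeds$fit)
  metrics <- lapply(list(train = tr, test = te), function(df) {
    pred <- predict(bundle, df)
    list(mae = mae_summary(pred, df$glucose, df$subject_id),
         bland_altman = bland_altman(pred, df$glucose))
  })
  explanation <- compute_attributions(bundle, tr)
  peaks <- find_peaks_q3iqr(tr$glucose, tr$subject_id,
                            min_peaks = config$min_peaks)
  importance <- overall_importance(explanation)
  freq <- peak_feature_frequency(explanation, peaks, k = config$k_top)
  manifest <- run_manifest(config, seeds, list(
    analysis = "glucose_prediction",
    n_subjects_retained = dplyr::n_distinct(feats$subject_id),
    n_predictors = length(attr(feats, "predictors")),
    n_subject_indicators = length(attr(feats, "subject_cols")),
    n_selected = length(selected),
    n_rows = list(train = nrow(tr), test = nrow(te))
  ))
  list(features = feats, rfe = rfe, tuning = tuning, bundle = bundle,
       explanation = explanation, peaks = peaks, importance = importance,
       peak_frequency = freq, metrics = metrics, stretches = prep$stretches,
       manifest = manifest)
}

#' Write run artifacts as plain-text files
#'
#' Writes the manifest and metrics as JSON and, for a glucose run, the tidy
#' importance tables and per-subject peak-frequency counts as CSV.
#'
#' @param run A [run_mealdetect()] or [run_glucose()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  if (!is.null(run$importance)) {
    readr::write_csv(run$importance$features,
                     file.path(dir, "importance_features.csv"))
    readr::write_csv(run$importance$groups,
                     file.path(dir, "importance_groups.csv"))
  }
  if (!is.null(run$peak_frequency)) {
    readr::write_csv(run$peak_frequency,
                     file.path(dir, "peak_feature_frequency.csv"))
  }
  invisible(dir)
}
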