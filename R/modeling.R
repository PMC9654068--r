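# Gradient-boosted tree modeling: gain-ranked recursive feature elimination
# with the within-10% selection rule, the two cross-validated hyperparameter
# search regimes (grid for classification, random for regression), model
# fitting and prediction, and bundle serialization.

#' @noRd
default_xgb_params <- function(task) {
  obj <- if (task == "meal_classification") "binary:logistic" else "reg:squarederror"
  list(objective = obj, max_depth = 6, eta = 0.3, min_child_weight = 1,
       subsample = 1, nthread = 1)
}

#' @noRd
check_task <- function(task) {
  match.arg(task, c("meal_classification", "glucose_regression"))
}

#' @noRd
as_feature_matrix <- function(x) {
  m <- data.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  m
}

#' @noRd
train_xgb <- function(x, y, task, params, nrounds, seed) {
  p <- utils::modifyList(default_xgb_params(task), params)
  p$seed <- seed
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  withr::with_seed(seed, {
    xgboost::xgb.train(params = p, data = dm, nrounds = nrounds, verbose = 0)
  })
}

# Held-out metric on the model's working scale: classification error at the
# 0.5 threshold, or MAE on the (log) regression target.
#' @noRd
holdout_metric <- function(pred, y, task) {
  if (task == "meal_classification") mean((pred >= 0.5) != y)
  else mean(abs(pred - y))
}

# k-fold partition of row indices, stratified when strata are given. Consumes
# the current RNG stream; callers seed it.
#' @noRd
make_folds <- function(n, k, strata = NULL) {
  if (k < 2 || k > n) stopf("cannot build %d folds from %d rows", k, n)
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  split(seq_len(n), fold)
}

#' @noRd
cv_metric <- function(x, y, task, folds, params, nrounds, seed) {
  per_fold <- vapply(seq_along(folds), function(f) {
    hold <- folds[[f]]
    bst <- train_xgb(x[-hold, , drop = FALSE], y[-hold], task, params,
                     nrounds, seed = child_seed(seed, f))
    pred <- predict(bst, xgboost::xgb.DMatrix(x[hold, , drop = FALSE],
                                              nthread = 1))
    holdout_metric(pred, y[hold], task)
  }, numeric(1))
  c(mean = mean(per_fold), sd = sd(per_fold))
}

#' @noRd
gain_importance <- function(booster, features) {
  imp <- tryCatch(xgboost::xgb.importance(model = booster),
                  error = function(e) NULL)
  gain <- setNames(rep(0, length(features)), features)
  if (!is.null(imp) && nrow(imp)) {
    gain[imp$Feature] <- imp$Gain
  }
  gain
}

#' Recursive feature elimination with the within-10% rule
#'
#' Repeatedly drops the lowest-gain 20% of the remaining features (at least
#' one per step, down to a single feature), recording 10-fold
#' cross-validated performance at each subset size with default
#' hyperparameters and a fixed number of boosting rounds. The selected set
#' is the smallest one whose mean CV error is within `tolerance` (default
#' 10%) of the best subset's error.
#'
#' @param x Feature matrix or data frame (columns named).
#' @param y Target: 0/1 labels for classification, log-glucose for
#'   regression.
#' @param task `"meal_classification"` or `"glucose_regression"`.
#' @param n_folds CV folds (default 10; stratified for classification).
#' @param nrounds Boosting rounds at every iteration (default 100).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param drop_frac Fraction of remaining features dropped per iteration.
#' @param tolerance Relative error slack defining "performs similarly".
#' @return An `rfe_result` list: `history` (size, CV mean and sd, feature
#'   list per size), `selected_features`, `selected_size`, `best_size`.
#' @export
rfe_select <- function(x, y, task, n_folds = 10, nrounds = 100, seed = 1,
                       drop_frac = 0.2, tolerance = 0.10) {
  task <- check_task(task)
  x <- as_feature_matrix(x)
  if (task == "meal_classification" && !all(y %in% c(0, 1)))
    stopf("classification target must be binary 0/1")
  strata <- if (task == "meal_classification") y else NULL
  folds <- withr::with_seed(child_seed(seed, 1L), {
    make_folds(nrow(x), n_folds, strata)
  })
  current <- colnames(x)
  history <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    xs <- x[, current, drop = FALSE]
    met <- cv_metric(xs, y, task, folds, params = list(), nrounds,
                     seed = child_seed(seed, 100L + it))
    history[[it]] <- tibble::tibble(
      size = length(current), metric_mean = met[["mean"]],
      metric_sd = met[["sd"]], features = list(current)
    )
    if (length(current) == 1L) break
    bst <- train_xgb(xs, y, task, list(), nrounds,
                     seed = child_seed(seed, 200L + it))
    gain <- gain_importance(bst, current)
    n_drop <- max(1L, floor(drop_frac * length(current)))
    n_drop <- min(n_drop, length(current) - 1L)
    drop <- current[order(gain)[seq_len(n_drop)]]
    current <- setdiff(current, drop)
  }
  history <- dplyr::bind_rows(history)
  best <- min(history$metric_mean)
  ok <- history$metric_mean <= (1 + tolerance) * best
  sel_row <- which(history$size == min(history$size[ok]) & ok)[1]
  structure(list(
    history = history[, c("size", "metric_mean", "metric_sd")],
    feature_sets = history$features,
    selected_features = history$features[[sel_row]],
    selected_size = history$size[sel_row],
    best_size = history$size[which.min(history$metric_mean)],
    task = task, tolerance = tolerance
  ), class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %s: %d of %d features selected (best size %d)\n",
              x$task, x$selected_size, max(x$history$size), x$best_size))
  invisible(x)
}

#' Cross-validated hyperparameter search
#'
#' Classification uses an exhaustive grid over max_depth x eta x
#' min_child_weight x subsample, minimizing the 10-fold CV classification
#' error; regression draws `n_random` random configurations (max_depth 2-8,
#' eta log-uniform on 0.03-0.3, min_child_weight 1-10, subsample and
#' colsample_bytree 0.6-1), minimizing the CV mean absolute error of the
#' log-glucose target. Ties go to the lower-complexity configuration
#' (smaller max_depth, then smaller min_child_weight), then to draw order.
#'
#' @inheritParams rfe_select
#' @param search `"grid"` or `"random"`; defaults to grid for classification
#'   and random search for regression.
#' @param n_random Number of random-search draws.
#' @param grid Optional data frame of configurations to use instead of the
#'   default grid.
#' @return A `tune_result` list: `params` (winning configuration),
#'   `cv_metric`, and the full `results` table.
#' @export
tune_hyperparams <- function(x, y, task, n_folds = 10, nrounds = 100,
                             seed = 1, search = NULL, n_random = 60,
                             grid = NULL) {
  task <- check_task(task)
  x <- as_feature_matrix(x)
  search <- search %||%
    (if (task == "meal_classification") "grid" else "random")
  search <- match.arg(search, c("grid", "random"))
  strata <- if (task == "meal_classification") y else NULL
  folds <- withr::with_seed(child_seed(seed, 2L), {
    make_folds(nrow(x), n_folds, strata)
  })
  configs <- if (search == "grid") {
    grid %||% expand.grid(max_depth = c(3L, 6L), eta = c(0.1, 0.3),
                          min_child_weight = c(1, 5), subsample = c(0.8, 1),
                          KEEP.OUT.ATTRS = FALSE)
  } else {
    withr::with_seed(child_seed(seed, 3L), {
      data.frame(
        max_depth = sample(2:8, n_random, replace = TRUE),
        eta = exp(runif(n_random, log(0.03), log(0.3))),
        min_child_weight = runif(n_random, 1, 10),
        subsample = runif(n_random, 0.6, 1),
        colsample_bytree = runif(n_random, 0.6, 1)
      )
    })
  }
  res <- configs
  res$cv_metric <- NA_real_
  res$cv_sd <- NA_real_
  for (i in seq_len(nrow(configs))) {
    met <- cv_metric(x, y, task, folds, params = as.list(configs[i, ]),
                     nrounds, seed = child_seed(seed, 300L + i))
    res$cv_metric[i] <- met[["mean"]]
    res$cv_sd[i] <- met[["sd"]]
  }
  pick <- order(res$cv_metric, res$max_depth, res$min_child_weight,
                seq_len(nrow(res)))[1]
  structure(list(
    params = as.list(configs[pick, ]),
    cv_metric = res$cv_metric[pick],
    results = tibble::as_tibble(res),
    search = search, task = task
  ), class = "tune_result")
}

#' Fit a gradient-boosted tree model
#'
#' Fits the task's xgboost model (binary logistic for meal detection,
#' squared-error regression on log glucose) with the given hyperparameters
#' and returns a self-describing bundle with gain importances.
#'
#' @inheritParams rfe_select
#' @param params Hyperparameter list (e.g. from [tune_hyperparams()]).
#' @return A `model_bundle`: fitted booster, feature names, params, rounds,
#'   per-feature gain importance, seed and a training-data fingerprint.
#' @export
fit_model <- function(x, y, task, params = list(), nrounds = 100, seed = 1) {
  task <- check_task(task)
  x <- as_feature_matrix(x)
  keep <- !is.na(y)
  if (any(!keep)) {
    message(sprintf("dropping %d rows with missing target", sum(!keep)))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (task == "meal_classification" && !all(y %in% c(0, 1)))
    stopf("classification target must be binary 0/1")
  booster <- train_xgb(x, y, task, params, nrounds, seed)
  structure(list(
    task = task, booster = booster, features = colnames(x),
    params = utils::modifyList(default_xgb_params(task), params),
    nrounds = nrounds, seed = seed,
    gain = gain_importance(booster, colnames(x)),
    fingerprint = list(n_rows = nrow(x), n_features = ncol(x),
                       target_mean = mean(y))
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s: %d features, %d rounds, trained on %d rows\n",
              x$task, length(x$features), x$nrounds, x$fingerprint$n_rows))
  invisible(x)
}

#' Predict from a model bundle
#'
#' @param object A `model_bundle`.
#' @param newdata Data frame or matrix containing at least the bundle's
#'   feature columns (extra columns are ignored; missing ones are an error).
#' @param type `"response"` (classification probability in `[0, 1]`, or
#'   glucose in mmol/L back-transformed from the log scale) or `"margin"`
#'   (the raw model score).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.model_bundle <- function(object, newdata, type = c("response", "margin"),
                                 ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, colnames(newdata))
  if (length(missing_cols))
    stopf("newdata lacks model features: %s",
          paste(missing_cols, collapse = ", "))
  m <- as_feature_matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  dm <- xgboost::xgb.DMatrix(m, nthread = 1)
  if (type == "margin") {
    predict(object$booster, dm, outputmargin = TRUE)
  } else if (object$task == "meal_classification") {
    predict(object$booster, dm)
  } else {
    exp(predict(object$booster, dm))
  }
}

#' Serialize / restore a model bundle
#'
#' The booster is written in xgboost's JSON format next to a JSON sidecar
#' holding features, hyperparameters, seed and fingerprint, so a reloaded
#' bundle reproduces predictions bit-identically.
#'
#' @param bundle A `model_bundle`.
#' @param dir Directory to write to (created if needed).
#' @return `dir` (for `save_bundle`) or the restored bundle.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(bundle$booster, file.path(dir, "model.json"))
  meta <- bundle[c("task", "features", "params", "nrounds", "seed",
                   "fingerprint")]
  meta$gain <- as.list(bundle$gain)
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "model.json"))
  structure(list(
    task = meta$task, booster = booster,
    features = as.character(meta$features),
    params = as.list(meta$params), nrounds = meta$nrounds, seed = meta$seed,
    gain = unlist(meta$gain), fingerprint = as.list(meta$fingerprint)
  ), class = "model_bundle")
}
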