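# Per-instance additive attribution for the fitted tree ensembles, grouped
# overall importance, per-subject Q3 + IQR glucose-peak detection and the
# per-peak top-k feature frequency report.

# Flatten an xgb.Booster into per-tree node arrays for the C++ kernels.
# Trees are read from the raw JSON model, whose numbers carry xgboost's
# shortest round-trip representation of the internal float32 values, so
# casting back to float32 reproduces the exact split thresholds and leaf
# values the booster uses.
#' @noRd
booster_trees <- function(booster, features) {
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(booster,
                                                          raw_format = "json")))
  model <- j$learner$gradient_booster$model
  if (is.null(model$trees))
    stopf("attributions require a tree-ensemble booster")
  nfeat <- as.integer(j$learner$learner_model_param$num_feature)
  if (nfeat != length(features))
    stopf("booster has %d features but the bundle lists %d", nfeat,
          length(features))
  trs <- model$trees
  lapply(seq_len(nrow(trs)), function(t) {
    left <- as.integer(trs$left_children[[t]])
    right <- as.integer(trs$right_children[[t]])
    leaf <- left < 0L
    cond <- as.numeric(trs$split_conditions[[t]])
    list(
      feature = as.integer(ifelse(leaf, -1L, as.integer(trs$split_indices[[t]]))),
      yes = left, no = right,
      missing = as.integer(ifelse(as.integer(trs$default_left[[t]]) == 1L,
                                  left, right)),
      split = cond,
      value = as.numeric(ifelse(leaf, cond, 0)),
      cover = as.numeric(trs$sum_hessian[[t]])
    )
  })
}

# Global intercept of the booster on the margin scale.
#' @noRd
booster_base_margin <- function(booster) {
  j <- jsonlite::fromJSON(rawToChar(xgboost::xgb.save.raw(booster,
                                                          raw_format = "json")))
  bs <- as.numeric(j$learner$learner_model_param$base_score)
  obj <- j$learner$objective$name
  if (grepl("^binary:logistic$", obj)) qlogis(bs) else bs
}

#' Exact Shapley attributions for a tree-ensemble model
#'
#' Computes per-row, per-feature additive contributions with the
#' path-dependent polynomial-time tree-Shapley algorithm, in double
#' precision. Contributions are on the model's margin scale (log-glucose
#' units for the regression task); for every row, the base value plus the
#' row's contributions equals the model's raw prediction (local accuracy).
#'
#' @param bundle A `model_bundle` from [fit_model()] (tree ensembles only).
#' @param newdata Rows to explain, containing the bundle's features.
#' @return A `shap_explanation`: `contributions` (rows x features matrix),
#'   scalar `base_value`, `raw_prediction` (the double-precision ensemble
#'   score per row), and `features`.
#' @export
compute_attributions <- function(bundle, newdata) {
  if (!inherits(bundle, "model_bundle") ||
      !inherits(bundle$booster, "xgb.Booster"))
    stopf("attributions are only supported for tree-ensemble model bundles")
  missing_cols <- setdiff(bundle$features, colnames(newdata))
  if (length(missing_cols))
    stopf("newdata lacks model features: %s",
          paste(missing_cols, collapse = ", "))
  m <- as_feature_matrix(as.data.frame(newdata)[, bundle$features,
                                                drop = FALSE])
  trees <- booster_trees(bundle$booster, bundle$features)
  phi <- .treeshap_cpp(trees, m)
  offset <- booster_base_margin(bundle$booster)
  contrib <- phi[, seq_along(bundle$features), drop = FALSE]
  colnames(contrib) <- bundle$features
  raw <- .tree_predict_cpp(trees, m) + offset
  structure(list(
    contributions = contrib,
    base_value = phi[1, ncol(phi)] + offset,
    raw_prediction = raw,
    features = bundle$features,
    task = bundle$task
  ), class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %d rows x %d features, base value %.4f\n",
              nrow(x$contributions), length(x$features), x$base_value))
  invisible(x)
}

#' Map glucose-model features to reporting groups
#'
#' Features are grouped for importance reporting: subject indicators ->
#' `subject`; sleep columns -> `sleep`; acceleration windows -> `activity
#' short-term` (windows up to 3 h) or `activity long-term` (8 h, 24 h);
#' calorie and fraction windows -> `nutrition short-term` / `nutrition
#' long-term` likewise; energy-expenditure and heart-rate windows ->
#' `cardiometabolic`. Unmapped names are an error, never silently pooled.
#'
#' @param features Character vector of feature names.
#' @return Character vector of group names.
#' @export
feature_group <- function(features) {
  win <- sub("^.*_(30m|60m|90m|2h|3h|8h|24h)_(sum|mean)$", "\\1", features)
  base <- sub("_(30m|60m|90m|2h|3h|8h|24h)_(sum|mean)$", "", features)
  term <- ifelse(win %in% .short_windows, "short-term", "long-term")
  grp <- rep(NA_character_, length(features))
  grp[grepl("^subj_", features)] <- "subject"
  grp[features %in% c("sleep_duration", "deep_sleep_duration")] <- "sleep"
  windowed <- win != features  # the window suffix actually matched
  nutr <- windowed & base %in% c("kcal_total", "kcal_carb", "kcal_fat",
                                 "kcal_protein", "frac_carb", "frac_fat",
                                 "frac_protein")
  grp[nutr] <- paste("nutrition", term[nutr])
  act <- windowed & base == "acceleration"
  grp[act] <- paste("activity", term[act])
  cardio <- windowed & base %in% c("energy_expenditure", "heart_rate")
  grp[cardio] <- "cardiometabolic"
  if (anyNA(grp))
    stopf("cannot map feature(s) to an importance group: %s",
          paste(features[is.na(grp)], collapse = ", "))
  grp
}

#' Overall and grouped feature importance from Shapley values
#'
#' Feature weight is the mean absolute contribution across all explained
#' rows; group weights sum the feature weights within [feature_group()]
#' groups and are normalized to percentages.
#'
#' @param explanation A [compute_attributions()] result.
#' @return An `importance_report`: `features` tibble (feature, group,
#'   weight, percent) and `groups` tibble (group, weight, percent summing
#'   to 100).
#' @export
overall_importance <- function(explanation) {
  stopifnot(inherits(explanation, "shap_explanation"))
  w <- colMeans(abs(explanation$contributions))
  feats <- tibble::tibble(
    feature = names(w),
    group = feature_group(names(w)),
    weight = unname(w),
    percent = if (sum(w) > 0) 100 * unname(w) / sum(w) else 0
  )
  groups <- feats |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$weight))
  groups$percent <- if (sum(groups$weight) > 0)
    100 * groups$weight / sum(groups$weight) else 0
  structure(list(features = dplyr::arrange(feats, dplyr::desc(.data$weight)),
                 groups = groups),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("<importance_report>\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

# Strict local maxima of a series; interior plateaus count once, at their
# first index.
#' @noRd
local_maxima_first <- function(x) {
  r <- rle(x)
  n <- length(r$values)
  if (n < 3) return(integer())
  starts <- cumsum(c(1L, r$lengths[-n]))
  j <- 2:(n - 1)
  j <- j[r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]]
  starts[j]
}

#' Per-subject glucose peaks above the Q3 + IQR threshold
#'
#' A peak is a strict local maximum of a subject's glucose series whose
#' value exceeds that subject's third quartile plus interquartile range
#' (type-7 quantiles of the full series). Subjects with fewer than
#' `min_peaks` peaks are flagged excluded from downstream per-peak
#' reporting.
#'
#' @param glucose Numeric glucose vector (mmol/L).
#' @param subject_id Parallel subject vector (optional; a single unnamed
#'   subject otherwise).
#' @param min_peaks Minimum peak count for a subject to be reported
#'   (default 10).
#' @return A `peak_set`: `peaks` tibble (subject_id, index into the input,
#'   value, threshold) and `subjects` tibble (quartiles, threshold,
#'   n_peaks, excluded flag).
#' @export
find_peaks_q3iqr <- function(glucose, subject_id = NULL, min_peaks = 10) {
  if (is.null(subject_id)) subject_id <- rep("all", length(glucose))
  stopifnot(length(glucose) == length(subject_id))
  subjects <- unique(subject_id)
  peaks <- list(); summaries <- list()
  for (sid in subjects) {
    idx <- which(subject_id == sid)
    x <- glucose[idx]
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
    thr <- q[2] + (q[2] - q[1])
    pk <- if (length(x) >= 3) local_maxima_first(x) else integer()
    pk <- pk[x[pk] > thr]
    peaks[[sid]] <- tibble::tibble(
      subject_id = sid, index = idx[pk], value = x[pk], threshold = thr
    )
    summaries[[sid]] <- tibble::tibble(
      subject_id = sid, q1 = q[1], q3 = q[2], threshold = thr,
      n_peaks = length(pk), excluded = length(pk) < min_peaks
    )
  }
  structure(list(peaks = dplyr::bind_rows(peaks),
                 subjects = dplyr::bind_rows(summaries),
                 min_peaks = min_peaks),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks across %d subjects (%d excluded at < %d peaks)\n",
              nrow(x$peaks), nrow(x$subjects), sum(x$subjects$excluded),
              x$min_peaks))
  invisible(x)
}

#' Frequency of the top-k features across a subject's glucose peaks
#'
#' For every retained subject and every one of its peaks, the `k` features
#' with the largest absolute Shapley contribution at that row are tallied
#' (ties broken by column order). Subjects flagged excluded in the peak set
#' are not reported.
#'
#' @param explanation A [compute_attributions()] result whose rows the peak
#'   indices refer to.
#' @param peak_set A [find_peaks_q3iqr()] result.
#' @param k Number of top features per peak (default 5; capped at the model
#'   size).
#' @return Tibble (subject_id, feature, count), with per-subject peak counts
#'   in `attr(, "n_peaks")`.
#' @export
peak_feature_frequency <- function(explanation, peak_set, k = 5) {
  stopifnot(inherits(explanation, "shap_explanation"),
            inherits(peak_set, "peak_set"))
  contrib <- explanation$contributions
  k <- min(k, ncol(contrib))
  keep <- peak_set$subjects$subject_id[!peak_set$subjects$excluded]
  pk <- peak_set$peaks[peak_set$peaks$subject_id %in% keep, , drop = FALSE]
  if (nrow(pk) && max(pk$index) > nrow(contrib))
    stopf("peak indices exceed the explained rows")
  rows <- lapply(seq_len(nrow(pk)), function(i) {
    a <- abs(contrib[pk$index[i], ])
    top <- order(-a, seq_along(a))[seq_len(k)]
    tibble::tibble(subject_id = pk$subject_id[i],
                   feature = colnames(contrib)[top])
  })
  counts <- dplyr::bind_rows(rows)
  counts <- if (nrow(counts)) {
    counts |>
      dplyr::count(.data$subject_id, .data$feature, name = "count") |>
      dplyr::arrange(.data$subject_id, dplyr::desc(.data$count))
  } else {
    tibble::tibble(subject_id = character(), feature = character(),
                   count = integer())
  }
  np <- pk |> dplyr::count(.data$subject_id, name = "n_peaks")
  attr(counts, "n_peaks") <- np
  attr(counts, "k") <- k
  counts
}
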