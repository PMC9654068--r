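# Feature engineering: the CGM-only meal-detection feature space with 30-min
# segment labels, and the 72 rolling nutrition/activity/sleep predictors for
# glucose prediction. All features are computed within a stretch; anything
# that would reach across a stretch boundary is left missing, never imputed.

.cgm_orders <- 1:6  # 6 x 15 min = the 90-min lead/lag horizon

#' Names of the CGM meal-detection features
#' @return Character vector of the 41 engineered CGM feature names.
#' @export
cgm_feature_names <- function() {
  c(paste0("lag", .cgm_orders), paste0("lead", .cgm_orders),
    paste0("dlead", .cgm_orders), paste0("dloglead", .cgm_orders),
    paste0("lagdlead", .cgm_orders),
    "sd_lead90", "mean_lead90", "sd_lag90", "mean_lag90",
    "sd_pm90", "mean_pm90", "rsd_lead90", "rsd_lag90",
    "ratio_sd", "ratio_max", "ratio_min")
}

#' Names of the 72 engineered glucose predictors
#'
#' 7 nutrition variables (4 kcal sums + 3 calorie-fraction means) and 3
#' activity variables (energy expenditure and acceleration sums, heart-rate
#' mean) over 7 trailing windows (30/60/90 min, 2/3/8/24 h), plus sleep
#' duration and deep-sleep duration: 49 + 21 + 2 = 72 columns.
#' @return Character vector of length 72.
#' @export
glucose_predictor_names <- function() {
  wl <- names(.windows_min)
  nutrition <- c(
    as.vector(outer(c("kcal_total", "kcal_carb", "kcal_fat", "kcal_protein"),
                    wl, function(b, w) paste0(b, "_", w, "_sum"))),
    as.vector(outer(c("frac_carb", "frac_fat", "frac_protein"),
                    wl, function(b, w) paste0(b, "_", w, "_mean")))
  )
  activity <- c(
    as.vector(outer(c("energy_expenditure", "acceleration"),
                    wl, function(b, w) paste0(b, "_", w, "_sum"))),
    paste0("heart_rate_", wl, "_mean")
  )
  c(nutrition, activity, "sleep_duration", "deep_sleep_duration")
}

# Ratio with the neutral-value convention for degenerate windows:
# 0/0 -> 1 (no spurious signal from constant windows); any other
# non-finite result -> NA.
#' @noRd
safe_ratio <- function(num, den) {
  r <- ifelse(!is.na(num) & !is.na(den) & num == 0 & den == 0, 1, num / den)
  r[!is.finite(r)] <- NA_real_
  r
}

#' CGM meal-detection features
#'
#' Computes, per stretch, lead/lag glucose values (orders 1-6), lead
#' differences and log-lead differences, lagged lead differences
#' (`g(t+k-1) - g(t-1)`), windowed means/SDs over the 90-min lead, lag and
#' combined windows, relative SDs, and lead/lag SD, max and min ratios.
#' Rows within 6 samples of a stretch boundary carry NA for features that
#' would cross it. Stretches shorter than 13 samples are dropped with a
#' warning.
#'
#' @param aligned Aligned frame with `subject_id`, `timestamp`, `glucose`
#'   and `stretch_id` columns (see [add_stretch_ids()]); rows outside any
#'   stretch are ignored.
#' @return Tibble with id columns and the [cgm_feature_names()] features,
#'   one row per in-stretch grid row.
#' @export
build_cgm_features <- function(aligned) {
  rows <- aligned[!is.na(aligned$stretch_id), , drop = FALSE]
  rows <- rows[order(rows$subject_id, rows$timestamp), , drop = FALSE]
  out <- lapply(split(rows, rows$stretch_id), function(df) {
    if (nrow(df) < 13) {
      warnf("stretch %s has %d rows (< 13); dropped from CGM features",
            df$stretch_id[1], nrow(df))
      return(NULL)
    }
    g <- df$glucose
    L <- sapply(.cgm_orders, function(k) shift_vec(g, -k))
    B <- sapply(.cgm_orders, function(k) shift_vec(g, k))
    feat <- tibble::tibble(.rows = nrow(df))
    for (k in .cgm_orders) feat[[paste0("lag", k)]] <- B[, k]
    for (k in .cgm_orders) feat[[paste0("lead", k)]] <- L[, k]
    for (k in .cgm_orders) feat[[paste0("dlead", k)]] <- L[, k] - g
    for (k in .cgm_orders) feat[[paste0("dloglead", k)]] <- log(L[, k]) - log(g)
    for (k in .cgm_orders) {
      feat[[paste0("lagdlead", k)]] <- shift_vec(g, -(k - 1L)) - shift_vec(g, 1L)
    }
    pm <- cbind(B[, 6:1], g, L)
    feat$sd_lead90 <- row_sd(L)
    feat$mean_lead90 <- rowMeans(L)
    feat$sd_lag90 <- row_sd(B)
    feat$mean_lag90 <- rowMeans(B)
    feat$sd_pm90 <- row_sd(pm)
    feat$mean_pm90 <- rowMeans(pm)
    feat$rsd_lead90 <- ifelse(feat$sd_lead90 == 0, 0,
                              feat$sd_lead90 / feat$mean_lead90)
    feat$rsd_lag90 <- ifelse(feat$sd_lag90 == 0, 0,
                             feat$sd_lag90 / feat$mean_lag90)
    feat$ratio_sd <- safe_ratio(feat$sd_lead90, feat$sd_lag90)
    feat$ratio_max <- safe_ratio(do.call(pmax, as.data.frame(L)),
                                 do.call(pmax, as.data.frame(B)))
    feat$ratio_min <- safe_ratio(do.call(pmin, as.data.frame(L)),
                                 do.call(pmin, as.data.frame(B)))
    dplyr::bind_cols(
      df[, intersect(c("subject_id", "timestamp", "stretch_id", "split",
                       "glucose"), names(df))],
      feat
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res)) res <- res[order(res$subject_id, res$timestamp), , drop = FALSE]
  attr(res, "predictors") <- cgm_feature_names()
  res
}

#' Eating-moment labels on the CGM grid
#'
#' A grid row is labeled positive when a carbohydrate-containing meal event
#' falls into its interval or into the interval of an immediately adjacent
#' row, so an isolated meal marks a 30-minute segment (the sample 15 min
#' before, the meal sample, and the sample 15 min after). Carb-free meals
#' produce no positives; events outside a subject's grid span are ignored
#' with a warning.
#'
#' @param grid_rows Tibble of grid rows (`subject_id`, `timestamp`).
#' @param meals Meal events from [aggregate_meals()].
#' @param grid_step Grid spacing in minutes.
#' @return Integer vector (0/1) aligned with `grid_rows`.
#' @export
build_meal_labels <- function(grid_rows, meals, grid_step = 15) {
  step_s <- grid_step * 60
  labels <- integer(nrow(grid_rows))
  carb_meals <- meals[meals$kcal_carb > 0, , drop = FALSE]
  if (nrow(carb_meals) == 0) return(labels)
  ts <- as.numeric(grid_rows$timestamp)
  for (sid in unique(carb_meals$subject_id)) {
    s_rows <- which(grid_rows$subject_id == sid)
    if (!length(s_rows)) next
    s_ts <- ts[s_rows]
    m_ts <- as.numeric(carb_meals$timestamp[carb_meals$subject_id == sid])
    anchor <- floor(m_ts / step_s) * step_s
    outside <- anchor < min(s_ts) | anchor > max(s_ts)
    if (any(outside))
      warnf("%d meal event(s) outside the grid span ignored for subject %s",
            sum(outside), sid)
    anchor <- anchor[!outside]
    pos_ts <- unique(c(anchor - step_s, anchor, anchor + step_s))
    labels[s_rows[s_ts %in% pos_ts]] <- 1L
  }
  labels
}

#' Rolling glucose-prediction predictors
#'
#' Builds the 72 engineered predictors of [glucose_predictor_names()] on the
#' aligned frame: trailing-window sums for calorie and activity quantities,
#' trailing-window means for calorie fractions (over meal-carrying rows
#' only; 0 when the window holds no meal) and heart rate, and the joined
#' sleep columns. Windows cover exactly `(t - W, t]` and never cross stretch
#' boundaries: rows with insufficient in-stretch history are missing. Also
#' appends one-hot subject indicator columns and the model target
#' `log_glucose`.
#'
#' @param aligned Aligned frame with `stretch_id` (see [add_stretch_ids()]).
#' @param grid_step Grid spacing in minutes.
#' @return Tibble of id columns, the 72 predictors, subject indicators and
#'   `log_glucose`; attributes `predictors` and `subject_cols` name the
#'   column sets.
#' @export
build_glucose_features <- function(aligned, grid_step = 15) {
  wl <- names(.windows_min)
  w_samp <- .windows_min / grid_step
  if (any(w_samp != round(w_samp)))
    stopf("grid_step must divide every rolling window")
  rows <- aligned[!is.na(aligned$stretch_id), , drop = FALSE]
  rows <- rows[order(rows$subject_id, rows$timestamp), , drop = FALSE]
  out <- lapply(split(rows, rows$stretch_id), function(df) {
    feat <- tibble::tibble(.rows = nrow(df))
    for (i in seq_along(wl)) {
      w <- as.integer(w_samp[i])
      for (b in c("kcal_total", "kcal_carb", "kcal_fat", "kcal_protein")) {
        feat[[paste0(b, "_", wl[i], "_sum")]] <- roll_sum(df[[b]], w)
      }
      for (b in c("frac_carb", "frac_fat", "frac_protein")) {
        feat[[paste0(b, "_", wl[i], "_mean")]] <-
          roll_mean_masked(df[[b]], df$meal_present, w)
      }
      for (b in c("energy_expenditure", "acceleration")) {
        feat[[paste0(b, "_", wl[i], "_sum")]] <- roll_sum(df[[b]], w)
      }
      feat[[paste0("heart_rate_", wl[i], "_mean")]] <- roll_mean(df$heart_rate, w)
    }
    feat$sleep_duration <- df$sleep_duration
    feat$deep_sleep_duration <- df$deep_sleep_duration
    dplyr::bind_cols(
      df[, intersect(c("subject_id", "timestamp", "stretch_id", "split",
                       "glucose"), names(df))],
      feat[, glucose_predictor_names()]
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res)) {
    res <- res[order(res$subject_id, res$timestamp), , drop = FALSE]
    subjects <- sort(unique(res$subject_id))
    subj_cols <- paste0("subj_", subjects)
    for (j in seq_along(subjects)) {
      res[[subj_cols[j]]] <- as.numeric(res$subject_id == subjects[j])
    }
    res$log_glucose <- log(res$glucose)
  } else {
    subj_cols <- character()
  }
  attr(res, "predictors") <- glucose_predictor_names()
  attr(res, "subject_cols") <- subj_cols
  res
}
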