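# Preprocessing: diary -> meal events, activity alignment to the CGM grid,
# sleep joining, uninterrupted-stretch selection and the two train/test
# splits.

# Atwater energy conversion factors, kcal per gram.
.atwater <- c(carb = 4, fat = 9, protein = 4)

#' Aggregate diary items into meal events
#'
#' Consecutive diary items of a subject that follow within 15 minutes of the
#' preceding item are chained into a single meal, stamped at the first item's
#' time. Calories are computed from grams with Atwater factors (4/9/4 kcal
#' per g of carbohydrate/fat/protein) and calorie fractions derived
#' (0 when the meal has no calories).
#'
#' @param diary Tibble with `subject_id`, `timestamp`, `carb_g`, `fat_g`,
#'   `protein_g`.
#' @param chain_minutes Maximum spacing (min) between consecutive items of
#'   one meal.
#' @return Tibble of meal events: `subject_id`, `timestamp`, grams, `kcal_*`
#'   totals and `frac_*` fractions.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   subject_id = "S01",
#'   timestamp = as.POSIXct("2023-03-06 12:00", tz = "UTC") + c(0, 600),
#'   carb_g = c(30, 10), fat_g = 0, protein_g = 0
#' )
#' aggregate_meals(d)  # one event at 12:00
aggregate_meals <- function(diary, chain_minutes = 15) {
  if (nrow(diary) == 0) {
    return(tibble::tibble(
      subject_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      carb_g = numeric(), fat_g = numeric(), protein_g = numeric(),
      kcal_total = numeric(), kcal_carb = numeric(), kcal_fat = numeric(),
      kcal_protein = numeric(), frac_carb = numeric(), frac_fat = numeric(),
      frac_protein = numeric()
    ))
  }
  if (any(diary$carb_g < 0 | diary$fat_g < 0 | diary$protein_g < 0))
    stopf("diary grams must be non-negative")
  ev <- diary |>
    dplyr::arrange(.data$subject_id, .data$timestamp) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      gap_min = as.numeric(difftime(.data$timestamp,
                                    dplyr::lag(.data$timestamp),
                                    units = "mins")),
      meal_id = cumsum(is.na(.data$gap_min) | .data$gap_min > chain_minutes)
    ) |>
    dplyr::group_by(.data$subject_id, .data$meal_id) |>
    dplyr::summarise(
      timestamp = dplyr::first(.data$timestamp),
      carb_g = sum(.data$carb_g),
      fat_g = sum(.data$fat_g),
      protein_g = sum(.data$protein_g),
      .groups = "drop"
    ) |>
    dplyr::select(-"meal_id")
  ev |>
    dplyr::mutate(
      kcal_carb = .atwater[["carb"]] * .data$carb_g,
      kcal_fat = .atwater[["fat"]] * .data$fat_g,
      kcal_protein = .atwater[["protein"]] * .data$protein_g,
      kcal_total = .data$kcal_carb + .data$kcal_fat + .data$kcal_protein,
      frac_carb = ifelse(.data$kcal_total > 0, .data$kcal_carb / .data$kcal_total, 0),
      frac_fat = ifelse(.data$kcal_total > 0, .data$kcal_fat / .data$kcal_total, 0),
      frac_protein = ifelse(.data$kcal_total > 0, .data$kcal_protein / .data$kcal_total, 0)
    ) |>
    dplyr::relocate("kcal_total", .before = "kcal_carb")
}

#' Aggregate activity samples onto a CGM grid
#'
#' For each half-open grid interval `[t, t + step)`, energy expenditure and
#' acceleration are summed (extensive quantities) and heart rate averaged
#' (intensive). Intervals with no sample are flagged unavailable.
#'
#' @param activity One subject's activity tibble (`timestamp`,
#'   `energy_expenditure`, `acceleration`, `heart_rate`).
#' @param grid Sorted vector of grid timestamps (POSIXct).
#' @param grid_step Grid spacing in minutes.
#' @return Tibble aligned to `grid` with columns `energy_expenditure`,
#'   `acceleration`, `heart_rate`, `activity_avail`.
#' @export
align_activity <- function(activity, grid, grid_step = 15) {
  n <- length(grid)
  out <- tibble::tibble(
    energy_expenditure = rep(NA_real_, n), acceleration = rep(NA_real_, n),
    heart_rate = rep(NA_real_, n), activity_avail = rep(FALSE, n)
  )
  if (nrow(activity) == 0 || n == 0) return(out)
  rel <- as.numeric(difftime(activity$timestamp, grid[1], units = "mins"))
  idx <- floor(rel / grid_step) + 1L
  ok <- idx >= 1L & idx <= n
  idx <- idx[ok]
  if (!length(idx)) return(out)
  ee <- rowsum(activity$energy_expenditure[ok], idx)
  ac <- rowsum(activity$acceleration[ok], idx)
  hr <- rowsum(activity$heart_rate[ok], idx)
  cnt <- rowsum(rep(1, length(idx)), idx)
  at <- as.integer(rownames(ee))
  out$energy_expenditure[at] <- ee[, 1]
  out$acceleration[at] <- ac[, 1]
  out$heart_rate[at] <- hr[, 1] / cnt[, 1]
  out$activity_avail[at] <- TRUE
  out
}

#' Join the closest preceding sleep record
#'
#' Each grid time receives the sleep record with the largest `sleep_end` not
#' after it, provided the record ended no more than `max_gap_hours` earlier;
#' otherwise the sleep columns are missing.
#'
#' @param grid Sorted POSIXct vector.
#' @param sleep One subject's sleep tibble (`sleep_end`, `sleep_duration`,
#'   `deep_sleep_duration`).
#' @param max_gap_hours Maximum allowed age of the sleep record (default 28).
#' @return Tibble aligned to `grid` with `sleep_duration`,
#'   `deep_sleep_duration`, `sleep_avail`.
#' @export
join_sleep <- function(grid, sleep, max_gap_hours = 28) {
  n <- length(grid)
  out <- tibble::tibble(
    sleep_duration = rep(NA_real_, n), deep_sleep_duration = rep(NA_real_, n),
    sleep_avail = rep(FALSE, n)
  )
  if (nrow(sleep) == 0 || n == 0) return(out)
  sl <- sleep[order(sleep$sleep_end), ]
  idx <- findInterval(as.numeric(grid), as.numeric(sl$sleep_end))
  age_h <- as.numeric(grid) - as.numeric(sl$sleep_end)[pmax(idx, 1L)]
  ok <- idx >= 1L & age_h <= max_gap_hours * 3600
  out$sleep_duration[ok] <- sl$sleep_duration[pmax(idx, 1L)][ok]
  out$deep_sleep_duration[ok] <- sl$deep_sleep_duration[pmax(idx, 1L)][ok]
  out$sleep_avail <- ok
  out
}

#' Build the 15-minute multimodal aligned frame
#'
#' Constructs, per subject, a regular grid spanning the observed glucose and
#' activity data, and joins glucose readings, aggregated activity, meal
#' events (from [aggregate_meals()]) and the closest preceding sleep record,
#' with per-modality availability flags.
#'
#' @param cohort A `raw_cohort` (or a list with `glucose`, `diary`,
#'   `activity`, `sleep` tibbles of that schema).
#' @param grid_step Grid spacing in minutes.
#' @param sleep_max_gap_hours Sleep-join window, hours.
#' @return An aligned tibble, one row per subject-grid interval.
#' @export
build_aligned_frame <- function(cohort, grid_step = 15, sleep_max_gap_hours = 28) {
  meals <- aggregate_meals(cohort$diary)
  subjects <- sort(unique(cohort$glucose$subject_id))
  step_s <- grid_step * 60
  out <- lapply(subjects, function(sid) {
    glu <- cohort$glucose[cohort$glucose$subject_id == sid, ]
    act <- cohort$activity[cohort$activity$subject_id == sid, ]
    slp <- cohort$sleep[cohort$sleep$subject_id == sid, ]
    mls <- meals[meals$subject_id == sid, ]
    t_all <- c(as.numeric(glu$timestamp), as.numeric(act$timestamp))
    if (!length(t_all)) return(NULL)
    t0 <- floor(min(t_all) / step_s) * step_s
    t1 <- floor(max(t_all) / step_s) * step_s
    grid <- as.POSIXct(seq(t0, t1, by = step_s), origin = "1970-01-01", tz = "UTC")
    n <- length(grid)

    # glucose: mean of readings per interval (the generator emits exactly one)
    gidx <- floor((as.numeric(glu$timestamp) - t0) / step_s) + 1L
    gsum <- rowsum(glu$glucose, gidx)
    gcnt <- rowsum(rep(1, length(gidx)), gidx)
    glucose <- rep(NA_real_, n)
    glucose[as.integer(rownames(gsum))] <- gsum[, 1] / gcnt[, 1]

    frame <- tibble::tibble(
      subject_id = sid, timestamp = grid,
      glucose = glucose, glucose_avail = !is.na(glucose)
    )
    frame <- dplyr::bind_cols(frame, align_activity(act, grid, grid_step))

    # meal events mapped to their grid interval
    kcal_cols <- c("kcal_total", "kcal_carb", "kcal_fat", "kcal_protein")
    for (cc in kcal_cols) frame[[cc]] <- 0
    for (cc in c("frac_carb", "frac_fat", "frac_protein")) frame[[cc]] <- 0
    if (nrow(mls)) {
      midx <- floor((as.numeric(mls$timestamp) - t0) / step_s) + 1L
      in_grid <- midx >= 1L & midx <= n
      if (any(!in_grid))
        warnf("%d meal event(s) outside the grid span ignored for subject %s",
              sum(!in_grid), sid)
      for (cc in kcal_cols) {
        s <- rowsum(mls[[cc]][in_grid], midx[in_grid])
        frame[[cc]][as.integer(rownames(s))] <- s[, 1]
      }
      tot <- frame$kcal_total
      frame$frac_carb <- ifelse(tot > 0, frame$kcal_carb / tot, 0)
      frame$frac_fat <- ifelse(tot > 0, frame$kcal_fat / tot, 0)
      frame$frac_protein <- ifelse(tot > 0, frame$kcal_protein / tot, 0)
    }
    frame$meal_present <- frame$kcal_total > 0
    dplyr::bind_cols(frame, join_sleep(grid, slp, sleep_max_gap_hours))
  })
  dplyr::bind_rows(out)
}

#' Select uninterrupted multimodal stretches
#'
#' A stretch is a maximal run of grid intervals where both the glucose sensor
#' and the activity tracker delivered data (a single missing CGM sample
#' breaks a stretch; the food diary has no sampling cadence and is treated as
#' always available while devices are worn). Stretches shorter than
#' `min_stretch_hours` are dropped, and subjects whose retained stretches
#' total no more than `min_total_days` days are excluded.
#'
#' @param aligned Output of [build_aligned_frame()].
#' @param grid_step Grid spacing in minutes.
#' @param min_stretch_hours Minimum stretch duration (default 24 h).
#' @param min_total_days Retention threshold: total stretch time must
#'   strictly exceed this many days (default 7).
#' @return A `stretch_set` tibble: `subject_id`, `stretch_id`, `start`,
#'   `end` (half-open), `n_rows`, `hours`; excluded subjects in
#'   `attr(, "excluded_subjects")`.
#' @export
select_stretches <- function(aligned, grid_step = 15, min_stretch_hours = 24,
                             min_total_days = 7) {
  step_s <- grid_step * 60
  res <- aligned |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(function(df, key) {
      flag <- df$glucose_avail & df$activity_avail
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      if (!length(keep)) return(NULL)
      tibble::tibble(
        subject_id = key$subject_id,
        start = df$timestamp[starts[keep]],
        end = df$timestamp[ends[keep]] + step_s,
        n_rows = r$lengths[keep]
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(res) == 0) {
    res <- tibble::tibble(subject_id = character(),
                          start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          n_rows = integer(), hours = numeric(),
                          stretch_id = character())
    attr(res, "excluded_subjects") <- unique(aligned$subject_id)
    class(res) <- c("stretch_set", class(res))
    return(res)
  }
  res$hours <- res$n_rows * grid_step / 60
  res <- res[res$hours >= min_stretch_hours, , drop = FALSE]
  totals <- res |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(total_hours = sum(.data$hours), .groups = "drop")
  retained <- totals$subject_id[totals$total_hours > min_total_days * 24]
  excluded <- setdiff(unique(aligned$subject_id), retained)
  res <- res[res$subject_id %in% retained, , drop = FALSE]
  res <- res |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(stretch_id = paste0(.data$subject_id, "-", dplyr::row_number())) |>
    dplyr::ungroup()
  attr(res, "excluded_subjects") <- excluded
  class(res) <- c("stretch_set", class(res))
  res
}

#' Tag aligned rows with their stretch
#'
#' @param aligned Output of [build_aligned_frame()].
#' @param stretches A [select_stretches()] result.
#' @return `aligned` with a `stretch_id` column (NA outside all stretches).
#' @export
add_stretch_ids <- function(aligned, stretches) {
  aligned$stretch_id <- NA_character_
  for (k in seq_len(nrow(stretches))) {
    hit <- aligned$subject_id == stretches$subject_id[k] &
      aligned$timestamp >= stretches$start[k] &
      aligned$timestamp < stretches$end[k]
    aligned$stretch_id[hit] <- stretches$stretch_id[k]
  }
  aligned
}

#' Train/test split for the glucose prediction analysis
#'
#' Per retained subject, the last `test_days` days of available (in-stretch)
#' data form the test set and all earlier in-stretch rows the training set.
#' Subjects with fewer than `test_days + 1` days of available data are
#' excluded with a warning (their training set would be empty).
#'
#' @param aligned Aligned frame with a `stretch_id` column
#'   (see [add_stretch_ids()]).
#' @param grid_step Grid spacing in minutes.
#' @param test_days Days held out at the end (default 3).
#' @return `aligned` with a `split` column (`"train"`, `"test"`, or NA).
#' @export
split_glucose <- function(aligned, grid_step = 15, test_days = 3) {
  per_day <- as.integer(1440 / grid_step)
  n_test <- test_days * per_day
  aligned$split <- NA_character_
  for (sid in unique(aligned$subject_id)) {
    rows <- which(aligned$subject_id == sid & !is.na(aligned$stretch_id))
    if (!length(rows)) next
    rows <- rows[order(aligned$timestamp[rows])]
    if (length(rows) < (test_days + 1) * per_day) {
      warnf("subject %s has < %d days of available data; excluded from the glucose split",
            sid, test_days + 1)
      next
    }
    test_rows <- tail(rows, n_test)
    aligned$split[rows] <- "train"
    aligned$split[test_rows] <- "test"
  }
  aligned
}

#' Train/test split for the meal-detection analysis
#'
#' Per retained subject, the first `train_days` days of available data train
#' the model and the subsequent `test_days` days test it; any later data are
#' left unused (the training window is kept intentionally small to mimic the
#' burden of diary keeping). Subjects with fewer than
#' `train_days + test_days` days of available data are excluded with a
#' warning.
#'
#' @inheritParams split_glucose
#' @param train_days Days used for training (default 4).
#' @param test_days Days used for testing (default 3).
#' @return `aligned` with a `split` column (`"train"`, `"test"`, `"unused"`,
#'   or NA).
#' @export
split_mealdetect <- function(aligned, grid_step = 15, train_days = 4,
                             test_days = 3) {
  per_day <- as.integer(1440 / grid_step)
  aligned$split <- NA_character_
  for (sid in unique(aligned$subject_id)) {
    rows <- which(aligned$subject_id == sid & !is.na(aligned$stretch_id))
    if (!length(rows)) next
    rows <- rows[order(aligned$timestamp[rows])]
    if (length(rows) < (train_days + test_days) * per_day) {
      warnf("subject %s has < %d days of available data; excluded from the meal-detection split",
            sid, train_days + test_days)
      next
    }
    aligned$split[rows] <- "unused"
    aligned$split[rows[seq_len(train_days * per_day)]] <- "train"
    aligned$split[rows[train_days * per_day + seq_len(test_days * per_day)]] <- "test"
  }
  aligned
}
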