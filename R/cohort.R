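# Synthetic free-living cohort generator: 15-min CGM traces with meal-driven
# excursions, a food diary, wrist-device activity samples, nightly sleep
# records, and optional per-modality device gaps. Ground-truth subject
# parameters are returned so downstream stages can be tested for signal
# recovery.

#' Configuration for a synthetic wearable cohort
#'
#' Bundles every tunable of [simulate_cohort()] with defaults that emulate a
#' 14-day free-living study of 24 healthy adults wearing a 15-minute CGM
#' sensor, a wrist activity tracker and keeping a food diary. Defaults produce
#' normoglycemic traces in roughly the 4-8 mmol/L range.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_days Days of monitoring per subject (>= 1).
#' @param grid_step CGM sampling interval in minutes; must divide 24 h.
#' @param meals_per_day Integer range `c(lo, hi)` of meals logged per day.
#' @param carb_grams,fat_grams,protein_grams Ranges (g) for per-meal macros.
#' @param baseline_glucose_mean,baseline_glucose_sd Subject fasting baseline
#'   distribution, mmol/L.
#' @param carb_sensitivity_mean,carb_sensitivity_sd Distribution of the
#'   dimensionless per-subject carbohydrate sensitivity (truncated at 0).
#' @param kernel_tau,kernel_tau_sd Meal-response time-to-peak (minutes);
#'   per-subject values are drawn around `kernel_tau`.
#' @param activity_beta Glucose depression per kcal of the trailing hour's
#'   energy expenditure (mmol/L per kcal). Set 0 to disable activity effects.
#' @param sleep_gamma Glucose shift per hour of sleep deficit relative to a
#'   7-h night (mmol/L per h).
#' @param noise_sd Marginal standard deviation of the AR(1) sensor noise
#'   (mmol/L).
#' @param noise_ar1 Lag-1 autocorrelation of the sensor noise, in `[0, 1)`.
#' @param activity_bouts_per_day Integer range of daily exercise bouts.
#' @param gap_spec Named list per modality (`glucose`, `activity`, `diary`,
#'   `sleep`), each with `prob` (per-day probability of a device gap) and
#'   `len_hours = c(lo, hi)` (gap length range).
#' @param start_date First monitoring day (UTC date or timestamp).
#' @param seed Integer seed making the whole simulation deterministic.
#'
#' @return A `cohort_config` list.
#' @seealso [simulate_cohort()], [inject_gaps()]
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, n_days = 3, seed = 7)
#' cfg$n_days
cohort_config <- function(n_subjects = 24,
                          n_days = 14,
                          grid_step = 15,
                          meals_per_day = c(3, 5),
                          carb_grams = c(20, 100),
                          fat_grams = c(5, 40),
                          protein_grams = c(5, 40),
                          baseline_glucose_mean = 5.0,
                          baseline_glucose_sd = 0.3,
                          carb_sensitivity_mean = 1.0,
                          carb_sensitivity_sd = 0.15,
                          kernel_tau = 45,
                          kernel_tau_sd = 5,
                          activity_beta = 0.002,
                          sleep_gamma = 0.05,
                          noise_sd = 0.15,
                          noise_ar1 = 0.5,
                          activity_bouts_per_day = c(0, 2),
                          gap_spec = list(
                            glucose = list(prob = 0.05, len_hours = c(2, 8)),
                            activity = list(prob = 0.05, len_hours = c(2, 8))
                          ),
                          start_date = "2023-03-06",
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
    grid_step = grid_step, meals_per_day = as.integer(meals_per_day),
    carb_grams = carb_grams, fat_grams = fat_grams,
    protein_grams = protein_grams,
    baseline_glucose_mean = baseline_glucose_mean,
    baseline_glucose_sd = baseline_glucose_sd,
    carb_sensitivity_mean = carb_sensitivity_mean,
    carb_sensitivity_sd = carb_sensitivity_sd,
    kernel_tau = kernel_tau, kernel_tau_sd = kernel_tau_sd,
    activity_beta = activity_beta, sleep_gamma = sleep_gamma,
    noise_sd = noise_sd, noise_ar1 = noise_ar1,
    activity_bouts_per_day = as.integer(activity_bouts_per_day),
    gap_spec = gap_spec, start_date = start_date, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @noRd
validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (cfg$n_days < 1L) stopf("n_days must be >= 1")
  if (cfg$grid_step <= 0 || (1440 %% cfg$grid_step) != 0)
    stopf("grid_step must be positive and divide 24 h (1440 min)")
  for (nm in c("baseline_glucose_sd", "carb_sensitivity_sd", "noise_sd",
               "kernel_tau_sd")) {
    if (cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  }
  if (cfg$noise_ar1 < 0 || cfg$noise_ar1 >= 1)
    stopf("noise_ar1 must lie in [0, 1)")
  if (cfg$kernel_tau <= 0) stopf("kernel_tau must be > 0")
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2] && r[1] >= 0
  for (nm in c("meals_per_day", "carb_grams", "fat_grams", "protein_grams",
               "activity_bouts_per_day")) {
    if (!rng_ok(cfg[[nm]])) stopf("%s must be a non-negative range c(lo, hi)", nm)
  }
  for (mod in names(cfg$gap_spec)) {
    gs <- cfg$gap_spec[[mod]]
    if (gs$prob < 0 || gs$prob > 1)
      stopf("gap probability for %s must lie in [0, 1]", mod)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d subjects x %d days, %g-min grid, seed %d\n",
    x$n_subjects, x$n_days, x$grid_step, x$seed
  ))
  invisible(x)
}

#' Incremental glucose response to a meal
#'
#' Gamma-type impulse response `A * u * exp(1 - u)` with `u = t / tau`,
#' rising from 0 at the meal, peaking at `t = tau` with amplitude
#' `A = s_i * carb_kcal / 100` mmol/L, and decaying back to 0.
#'
#' @param t_since_meal Minutes since meal start (vectorised; negative times
#'   contribute 0).
#' @param carb_kcal Carbohydrate calories of the meal (>= 0).
#' @param s_i Dimensionless subject carbohydrate sensitivity.
#' @param tau Time-to-peak in minutes (> 0).
#' @return Incremental glucose in mmol/L, same length as `t_since_meal`.
#' @export
#' @examples
#' glucose_kernel(45, carb_kcal = 200, s_i = 1, tau = 45)  # peak: 2 mmol/L
glucose_kernel <- function(t_since_meal, carb_kcal, s_i = 1, tau = 45) {
  if (tau <= 0) stopf("tau must be > 0")
  if (any(carb_kcal < 0)) stopf("carb_kcal must be >= 0")
  amp <- s_i * carb_kcal / 100
  u <- t_since_meal / tau
  ifelse(t_since_meal < 0, 0, amp * u * exp(1 - u))
}

#' Simulate a multimodal wearable cohort
#'
#' Generates the four observation streams of a free-living study -- CGM
#' glucose on a regular grid, food-diary items, 5-minute activity samples and
#' nightly sleep records -- from a known generative model:
#' `g_i(t) = b_i + gamma_i * (7 - sleep_h) + sum(meal kernels)
#'  - beta_i * EE_hour(t) + AR(1) noise`,
#' clamped to stay positive. Meals are placed at jittered breakfast / lunch /
#' dinner (plus snack) times, logged as 1-3 diary items within 10 minutes,
#' and drive glucose through [glucose_kernel()]. Activity bouts raise energy
#' expenditure, acceleration counts and heart rate together and depress
#' glucose through the trailing-hour energy expenditure.
#'
#' The output is deterministic given `config$seed` and contains no device
#' gaps; apply [inject_gaps()] for those.
#'
#' @param config A [cohort_config()].
#' @return A `raw_cohort` list with tibbles `glucose`, `diary`, `activity`,
#'   `sleep`, per-subject ground `truth`, and the `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 1, n_days = 2, seed = 1))
#' nrow(coh$glucose)  # 2 days x 96 samples
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

#' @noRd
simulate_cohort_impl <- function(cfg) {
  start <- as.POSIXct(as.character(cfg$start_date), tz = "UTC")
  step <- cfg$grid_step
  day_min <- 1440
  span_min <- cfg$n_days * day_min
  grid_min <- seq(0, span_min - step, by = step)
  act_step <- 5
  act_min <- seq(0, span_min - act_step, by = act_step)

  draw_range <- function(r, n) runif(n, r[1], r[2])
  draw_count <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L

  glucose <- diary <- activity <- sleep <- truth <- vector("list", cfg$n_subjects)

  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", i)

    b_i <- max(2, rnorm(1, cfg$baseline_glucose_mean, cfg$baseline_glucose_sd))
    s_i <- max(0, rnorm(1, cfg$carb_sensitivity_mean, cfg$carb_sensitivity_sd))
    beta_i <- max(0, rnorm(1, cfg$activity_beta, 0.2 * abs(cfg$activity_beta)))
    gamma_i <- rnorm(1, cfg$sleep_gamma, 0.2 * abs(cfg$sleep_gamma))
    tau_i <- max(10, rnorm(1, cfg$kernel_tau, cfg$kernel_tau_sd))
    truth[[i]] <- tibble::tibble(
      subject_id = sid, baseline = b_i, carb_sensitivity = s_i,
      activity_beta = beta_i, sleep_gamma = gamma_i, kernel_tau = tau_i
    )

    # Nightly sleep: one record per study day, ending around 07:00.
    sleep_end_min <- (seq_len(cfg$n_days) - 1L) * day_min + 7 * 60 +
      rnorm(cfg$n_days, 0, 30)
    sleep_dur <- pmin(10, pmax(4, rnorm(cfg$n_days, 7.5, 1)))
    deep_dur <- runif(cfg$n_days, 0.15, 0.30) * sleep_dur
    sleep[[i]] <- tibble::tibble(
      subject_id = sid,
      sleep_end = start + round(sleep_end_min * 60),
      sleep_duration = sleep_dur,
      deep_sleep_duration = deep_dur
    )

    # Meals: mains at 07:30 / 12:30 / 18:30, snacks at 10:00 / 15:30, all
    # jittered (sd 30 min) and pushed at least 45 min apart so excursions
    # stay separable.
    meal_time <- c(); meal_carb <- c(); meal_fat <- c(); meal_prot <- c()
    slots <- c(450, 750, 1110, 600, 930)
    for (d in seq_len(cfg$n_days) - 1L) {
      n_meals <- min(draw_count(cfg$meals_per_day), length(slots))
      if (n_meals == 0L) next
      t_day <- sort(slots[seq_len(n_meals)] + rnorm(n_meals, 0, 30))
      if (length(t_day) > 1L) {
        for (j in 2:length(t_day)) t_day[j] <- max(t_day[j], t_day[j - 1] + 45)
      }
      t_day <- pmin(pmax(round(t_day), 0), day_min - 15)
      meal_time <- c(meal_time, d * day_min + t_day)
      meal_carb <- c(meal_carb, draw_range(cfg$carb_grams, n_meals))
      meal_fat <- c(meal_fat, draw_range(cfg$fat_grams, n_meals))
      meal_prot <- c(meal_prot, draw_range(cfg$protein_grams, n_meals))
    }

    # Diary items: each meal logged as 1-3 items spaced 5 min apart, grams
    # split evenly (so aggregation recovers the meal exactly).
    items <- list()
    for (m in seq_along(meal_time)) {
      n_items <- sample.int(3L, 1L)
      off <- c(0, 5, 10)[seq_len(n_items)]
      items[[m]] <- tibble::tibble(
        subject_id = sid,
        timestamp = start + (meal_time[m] + off) * 60,
        carb_g = meal_carb[m] / n_items,
        fat_g = meal_fat[m] / n_items,
        protein_g = meal_prot[m] / n_items
      )
    }
    diary[[i]] <- if (length(items)) dplyr::bind_rows(items) else
      tibble::tibble(subject_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                     carb_g = numeric(), fat_g = numeric(), protein_g = numeric())

    # Activity at 5-min cadence: resting EE ~ 6 kcal / 5 min plus 0-2 daily
    # bouts of 30-60 min with elevated EE, acceleration and heart rate.
    n_act <- length(act_min)
    ee <- pmax(0.5, rnorm(n_act, 6, 0.5))
    acn <- pmax(0, rnorm(n_act, 20, 10))
    bout_mult <- rep(1, n_act)
    for (d in seq_len(cfg$n_days) - 1L) {
      n_bouts <- draw_count(cfg$activity_bouts_per_day)
      if (n_bouts == 0L) next
      b_start <- runif(n_bouts, 8 * 60, 21 * 60)
      b_len <- runif(n_bouts, 30, 60)
      b_mult <- runif(n_bouts, 4, 8)
      for (k in seq_len(n_bouts)) {
        in_bout <- act_min >= d * day_min + b_start[k] &
          act_min < d * day_min + b_start[k] + b_len[k]
        bout_mult[in_bout] <- pmax(bout_mult[in_bout], b_mult[k])
        acn[in_bout] <- acn[in_bout] + runif(1, 200, 400)
      }
    }
    ee <- ee * bout_mult
    hr <- 60 + 0.15 * acn + rnorm(n_act, 0, 2)
    activity[[i]] <- tibble::tibble(
      subject_id = sid,
      timestamp = start + act_min * 60,
      energy_expenditure = ee,
      acceleration = acn,
      heart_rate = hr
    )

    # Glucose on the CGM grid.
    g <- rep(b_i, length(grid_min))

    # Previous-night sleep effect via the closest preceding record (<= 28 h);
    # a 7-h night is neutral.
    idx <- findInterval(grid_min, sleep_end_min)
    dur_prev <- ifelse(
      idx >= 1 & (grid_min - sleep_end_min[pmax(idx, 1L)]) <= 28 * 60,
      sleep_dur[pmax(idx, 1L)], 7
    )
    g <- g + gamma_i * (7 - dur_prev)

    for (m in seq_along(meal_time)) {
      g <- g + glucose_kernel(grid_min - meal_time[m], 4 * meal_carb[m],
                              s_i, tau_i)
    }

    # Trailing-hour energy expenditure from the 5-min samples.
    cs_ee <- c(0, cumsum(ee))
    hi <- findInterval(grid_min, act_min)
    lo <- findInterval(grid_min - 60, act_min)
    ee_hour <- cs_ee[hi + 1L] - cs_ee[lo + 1L]
    g <- g - beta_i * ee_hour

    if (cfg$noise_sd > 0) {
      z <- rnorm(length(g))
      e <- numeric(length(g))
      e[1] <- cfg$noise_sd * z[1]
      if (length(g) > 1) {
        a <- cfg$noise_ar1
        innov_sd <- cfg$noise_sd * sqrt(1 - a^2)
        for (t in 2:length(g)) e[t] <- a * e[t - 1] + innov_sd * z[t]
      }
      g <- g + e
    } else {
      rnorm(length(g))  # keep the draw sequence aligned across noise settings
    }

    glucose[[i]] <- tibble::tibble(
      subject_id = sid,
      timestamp = start + grid_min * 60,
      glucose = pmax(g, 0.3)
    )
  }

  new_raw_cohort(
    glucose = dplyr::bind_rows(glucose),
    diary = dplyr::bind_rows(diary),
    activity = dplyr::bind_rows(activity),
    sleep = dplyr::bind_rows(sleep),
    truth = dplyr::bind_rows(truth),
    config = cfg
  )
}

#' @noRd
new_raw_cohort <- function(glucose, diary, activity, sleep, truth, config) {
  for (tab in list(glucose, diary, activity, sleep)) {
    nm <- intersect(c("timestamp", "sleep_end"), names(tab))[1]
    bad <- tab |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(ok = !is.unsorted(.data[[nm]], strictly = TRUE),
                       .groups = "drop")
    if (any(!bad$ok)) stopf("timestamps must be strictly increasing per subject")
  }
  if (any(glucose$glucose <= 0)) stopf("glucose must be positive everywhere")
  if (any(sleep$deep_sleep_duration > sleep$sleep_duration + 1e-9))
    stopf("deep sleep cannot exceed total sleep")
  structure(
    list(glucose = glucose, diary = diary, activity = activity,
         sleep = sleep, truth = truth, config = config),
    class = "raw_cohort"
  )
}

#' @export
print.raw_cohort <- function(x, ...) {
  cat(sprintf(
    "<raw_cohort> %d subjects; %d glucose, %d diary, %d activity rows; %d sleep records\n",
    dplyr::n_distinct(x$glucose$subject_id), nrow(x$glucose), nrow(x$diary),
    nrow(x$activity), nrow(x$sleep)
  ))
  invisible(x)
}

#' Inject contiguous device gaps into a cohort
#'
#' Removes rows of the chosen modalities in contiguous time blocks,
#' emulating whole-device failure episodes. The ground truth and config are
#' untouched; the result is deterministic given `seed`.
#'
#' @param cohort A `raw_cohort`.
#' @param gap_spec As in [cohort_config()]; defaults to the cohort's own.
#' @param seed Integer seed.
#' @return The cohort with rows removed.
#' @export
inject_gaps <- function(cohort, gap_spec = cohort$config$gap_spec,
                        seed = cohort$config$seed) {
  stopifnot(inherits(cohort, "raw_cohort"))
  for (mod in names(gap_spec)) {
    gs <- gap_spec[[mod]]
    if (gs$prob < 0 || gs$prob > 1) stopf("gap probability must lie in [0, 1]")
  }
  withr::with_seed(child_seed(seed, 7L), {
    cfg <- cohort$config
    span_sec <- cfg$n_days * 86400
    start <- as.POSIXct(as.character(cfg$start_date), tz = "UTC")
    subjects <- unique(cohort$glucose$subject_id)
    for (mod in intersect(names(gap_spec), c("glucose", "activity", "diary", "sleep"))) {
      gs <- gap_spec[[mod]]
      tab_name <- if (mod == "diary") "diary" else mod
      tab <- cohort[[tab_name]]
      ts_col <- if (mod == "sleep") "sleep_end" else "timestamp"
      keep <- rep(TRUE, nrow(tab))
      for (sid in subjects) {
        n_gaps <- rbinom(1, cfg$n_days, gs$prob)
        if (n_gaps == 0L) next
        g_start <- runif(n_gaps, 0, span_sec)
        g_len <- runif(n_gaps, gs$len_hours[1], gs$len_hours[2]) * 3600
        rel <- as.numeric(difftime(tab[[ts_col]], start, units = "secs"))
        for (k in seq_len(n_gaps)) {
          keep <- keep & !(tab$subject_id == sid &
                             rel >= g_start[k] & rel < g_start[k] + g_len[k])
        }
      }
      cohort[[tab_name]] <- tab[keep, , drop = FALSE]
    }
    cohort
  })
}

#' Write / read a cohort as plain-text tables
#'
#' The four observation tables plus the truth table are written as RFC-4180
#' CSV with ISO-8601 UTC timestamps (and optionally Parquet when the `arrow`
#' package is available); the config is stored as JSON.
#'
#' @param cohort A `raw_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "raw_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("glucose", "diary", "activity", "sleep", "truth")
  for (nm in tabs) {
    if (format == "csv") {
      readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
    } else {
      if (!requireNamespace("arrow", quietly = TRUE))
        stopf("parquet output requires the 'arrow' package")
      arrow::write_parquet(cohort[[nm]], file.path(dir, paste0(nm, ".parquet")))
    }
  }
  cfg <- cohort$config
  cfg$start_date <- as.character(cfg$start_date)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  read_tab <- function(nm) {
    if (format == "csv") {
      readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                      show_col_types = FALSE)
    } else {
      arrow::read_parquet(file.path(dir, paste0(nm, ".parquet")))
    }
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$gap_spec <- lapply(cfg$gap_spec, function(g) {
    list(prob = g$prob, len_hours = unlist(g$len_hours))
  })
  cfg <- do.call(cohort_config, cfg[setdiff(names(cfg), NULL)])
  new_raw_cohort(read_tab("glucose"), read_tab("diary"), read_tab("activity"),
                 read_tab("sleep"), read_tab("truth"), cfg)
}
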