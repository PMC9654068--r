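# Independent brute-force reference implementations used as oracles. These
# materialize every window / neighbour explicitly with loops and never share
# code with the package internals.

# --- CGM feature oracle -----------------------------------------------------

bf_win <- function(g, idx) {
  n <- length(g)
  if (any(idx < 1 | idx > n)) return(NULL)
  g[idx]
}

bf_ratio <- function(num, den) {
  if (is.na(num) || is.na(den)) return(NA_real_)
  if (num == 0 && den == 0) return(1)
  r <- num / den
  if (!is.finite(r)) NA_real_ else r
}

bf_cgm_row <- function(g, i) {
  n <- length(g)
  out <- list()
  for (k in 1:6) {
    out[[paste0("lag", k)]] <- if (i - k >= 1) g[i - k] else NA_real_
    out[[paste0("lead", k)]] <- if (i + k <= n) g[i + k] else NA_real_
    out[[paste0("dlead", k)]] <- if (i + k <= n) g[i + k] - g[i] else NA_real_
    out[[paste0("dloglead", k)]] <-
      if (i + k <= n) log(g[i + k]) - log(g[i]) else NA_real_
    out[[paste0("lagdlead", k)]] <-
      if (i + k - 1 <= n && i - 1 >= 1) g[i + k - 1] - g[i - 1] else NA_real_
  }
  lead_w <- bf_win(g, (i + 1):(i + 6))
  lag_w <- bf_win(g, (i - 6):(i - 1))
  pm_w <- bf_win(g, (i - 6):(i + 6))
  out$sd_lead90 <- if (is.null(lead_w)) NA_real_ else sd(lead_w)
  out$mean_lead90 <- if (is.null(lead_w)) NA_real_ else mean(lead_w)
  out$sd_lag90 <- if (is.null(lag_w)) NA_real_ else sd(lag_w)
  out$mean_lag90 <- if (is.null(lag_w)) NA_real_ else mean(lag_w)
  out$sd_pm90 <- if (is.null(pm_w)) NA_real_ else sd(pm_w)
  out$mean_pm90 <- if (is.null(pm_w)) NA_real_ else mean(pm_w)
  out$rsd_lead90 <- if (is.na(out$sd_lead90)) NA_real_ else
    if (out$sd_lead90 == 0) 0 else out$sd_lead90 / out$mean_lead90
  out$rsd_lag90 <- if (is.na(out$sd_lag90)) NA_real_ else
    if (out$sd_lag90 == 0) 0 else out$sd_lag90 / out$mean_lag90
  out$ratio_sd <- bf_ratio(out$sd_lead90, out$sd_lag90)
  out$ratio_max <- bf_ratio(
    if (is.null(lead_w)) NA_real_ else max(lead_w),
    if (is.null(lag_w)) NA_real_ else max(lag_w))
  out$ratio_min <- bf_ratio(
    if (is.null(lead_w)) NA_real_ else min(lead_w),
    if (is.null(lag_w)) NA_real_ else min(lag_w))
  out
}

bf_cgm_features <- function(g) {
  rows <- lapply(seq_along(g), function(i) tibble::as_tibble(bf_cgm_row(g, i)))
  dplyr::bind_rows(rows)
}

# --- rolling-window oracle --------------------------------------------------

bf_glucose_row <- function(df, i, grid_step = 15) {
  wins <- c("30m" = 30, "60m" = 60, "90m" = 90, "2h" = 120, "3h" = 180,
            "8h" = 480, "24h" = 1440)
  out <- list()
  for (wl in names(wins)) {
    w <- wins[[wl]] / grid_step
    idx <- (i - w + 1):i
    full <- all(idx >= 1)
    for (b in c("kcal_total", "kcal_carb", "kcal_fat", "kcal_protein",
                "energy_expenditure", "acceleration")) {
      out[[paste0(b, "_", wl, "_sum")]] <-
        if (full) sum(df[[b]][idx]) else NA_real_
    }
    for (b in c("frac_carb", "frac_fat", "frac_protein")) {
      if (!full) {
        v <- NA_real_
      } else {
        meal_idx <- idx[df$meal_present[idx]]
        v <- if (length(meal_idx)) mean(df[[b]][meal_idx]) else 0
      }
      out[[paste0(b, "_", wl, "_mean")]] <- v
    }
    out[[paste0("heart_rate_", wl, "_mean")]] <-
      if (full) mean(df$heart_rate[idx]) else NA_real_
  }
  out$sleep_duration <- df$sleep_duration[i]
  out$deep_sleep_duration <- df$deep_sleep_duration[i]
  out
}

bf_glucose_features <- function(df, grid_step = 15) {
  rows <- lapply(seq_len(nrow(df)),
                 function(i) tibble::as_tibble(bf_glucose_row(df, i, grid_step)))
  dplyr::bind_rows(rows)
}

# --- peak oracle ------------------------------------------------------------

bf_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

bf_peaks <- function(x) {
  q1 <- bf_quantile7(x, 0.25)
  q3 <- bf_quantile7(x, 0.75)
  thr <- q3 + (q3 - q1)
  n <- length(x)
  peaks <- integer()
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1  # walk the plateau
      if (j < n && x[j + 1] < x[i]) {
        if (x[i] > thr) peaks <- c(peaks, i)
        i <- j + 1
        next
      }
      i <- j + 1
      next
    }
    i <- i + 1
  }
  list(threshold = thr, peaks = peaks)
}

# --- small data constructors ------------------------------------------------

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# A minimal aligned frame with a single stretch, driven by explicit vectors.
toy_aligned <- function(glucose, grid_step = 15,
                        start = ts_utc("2023-03-06 00:00:00"),
                        subject_id = "S01", stretch_id = "S01-1") {
  n <- length(glucose)
  tibble::tibble(
    subject_id = subject_id,
    timestamp = start + (seq_len(n) - 1) * grid_step * 60,
    glucose = glucose, glucose_avail = TRUE,
    energy_expenditure = 0, acceleration = 0, heart_rate = 60,
    activity_avail = TRUE,
    kcal_total = 0, kcal_carb = 0, kcal_fat = 0, kcal_protein = 0,
    frac_carb = 0, frac_fat = 0, frac_protein = 0, meal_present = FALSE,
    sleep_duration = NA_real_, deep_sleep_duration = NA_real_,
    sleep_avail = FALSE,
    stretch_id = stretch_id
  )
}

diary_row <- function(time, carb = 0, fat = 0, protein = 0, sid = "S01") {
  tibble::tibble(subject_id = sid, timestamp = ts_utc(time),
                 carb_g = carb, fat_g = fat, protein_g = protein)
}

# quick deterministic regression fit on a random design
toy_regression_bundle <- function(n = 300, p = 5, seed = 1, nrounds = 30,
                                  params = list()) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.1)
    list(x = x, y = y,
         bundle = fit_model(x, y, "glucose_regression", params = params,
                            nrounds = nrounds, seed = seed))
  })
}
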