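# Meal aggregation, grid alignment, sleep joining, stretch selection and the
# two train/test splits.

test_that("diary items within 15 min chain into one meal, beyond stay separate", {
  d <- dplyr::bind_rows(
    diary_row("2023-03-06 12:00:00", carb = 30),
    diary_row("2023-03-06 12:10:00", carb = 10)
  )
  ev <- aggregate_meals(d)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$timestamp, ts_utc("2023-03-06 12:00:00"))
  expect_equal(ev$carb_g, 40)

  d2 <- dplyr::bind_rows(
    diary_row("2023-03-06 12:00:00", carb = 30),
    diary_row("2023-03-06 12:20:00", carb = 10)
  )
  expect_equal(nrow(aggregate_meals(d2)), 2L)

  # chaining is transitive: 12:00 + 12:10 + 12:22 is still one meal
  d3 <- dplyr::bind_rows(d, diary_row("2023-03-06 12:22:00", carb = 5))
  expect_equal(nrow(aggregate_meals(d3)), 1L)
})

test_that("Atwater arithmetic and fraction conventions hold", {
  ev <- aggregate_meals(diary_row("2023-03-06 08:00:00", carb = 10))
  expect_equal(ev$kcal_total, 40)
  expect_equal(ev$frac_carb, 1)
  expect_equal(ev$frac_fat + ev$frac_protein, 0)

  mixed <- aggregate_meals(
    diary_row("2023-03-06 08:00:00", carb = 10, fat = 10, protein = 10))
  expect_equal(mixed$kcal_total, 40 + 90 + 40)
  expect_equal(mixed$frac_carb + mixed$frac_fat + mixed$frac_protein, 1,
               tolerance = 1e-9)

  zero <- aggregate_meals(diary_row("2023-03-06 08:00:00"))
  expect_equal(zero$kcal_total, 0)
  expect_equal(zero$frac_carb, 0)

  expect_error(aggregate_meals(diary_row("2023-03-06 08:00:00", carb = -1)),
               "non-negative")
})

test_that("meal aggregation is idempotent and conserves calories", {
  set.seed(42)
  d <- tibble::tibble(
    subject_id = sample(c("S01", "S02"), 40, replace = TRUE),
    timestamp = ts_utc("2023-03-06 06:00:00") + sort(runif(40, 0, 86400 * 2)),
    carb_g = runif(40, 0, 50), fat_g = runif(40, 0, 30),
    protein_g = runif(40, 0, 30)
  )
  ev <- aggregate_meals(d)
  again <- aggregate_meals(ev[, c("subject_id", "timestamp", "carb_g",
                                  "fat_g", "protein_g")])
  expect_equal(again$timestamp, ev$timestamp)
  expect_equal(again$kcal_total, ev$kcal_total)
  expect_equal(sum(ev$kcal_total),
               sum(4 * d$carb_g + 9 * d$fat_g + 4 * d$protein_g))
})

test_that("activity aggregates by sum (EE, acceleration) and mean (heart rate)", {
  grid <- ts_utc("2023-03-06 00:00:00") + (0:3) * 900
  act <- tibble::tibble(
    subject_id = "S01",
    timestamp = ts_utc("2023-03-06 00:00:00") + c(0, 300, 600, 900, 1200),
    energy_expenditure = c(1, 1, 1, 2, 2),
    acceleration = c(10, 20, 30, 5, 5),
    heart_rate = c(60, 70, 80, 55, 65)
  )
  out <- align_activity(act, grid)
  expect_equal(out$energy_expenditure[1:2], c(3, 4))
  expect_equal(out$acceleration[1:2], c(60, 10))
  expect_equal(out$heart_rate[1:2], c(70, 60))
  expect_false(out$activity_avail[3])
  expect_true(is.na(out$energy_expenditure[4]))
})

test_that("activity alignment matches a per-interval brute-force aggregation", {
  set.seed(7)
  for (rep in 1:20) {
    n_grid <- sample(5:30, 1)
    grid <- ts_utc("2023-03-06 00:00:00") + (seq_len(n_grid) - 1) * 900
    n_s <- sample(0:80, 1)
    act <- tibble::tibble(
      subject_id = "S01",
      timestamp = ts_utc("2023-03-06 00:00:00") +
        sort(runif(n_s, -900, n_grid * 900 + 900)),
      energy_expenditure = runif(n_s), acceleration = runif(n_s, 0, 100),
      heart_rate = runif(n_s, 50, 120)
    )
    out <- align_activity(act, grid)
    for (i in seq_len(n_grid)) {
      inside <- act$timestamp >= grid[i] & act$timestamp < grid[i] + 900
      if (!any(inside)) {
        expect_false(out$activity_avail[i])
      } else {
        expect_equal(out$energy_expenditure[i],
                     sum(act$energy_expenditure[inside]))
        expect_equal(out$acceleration[i], sum(act$acceleration[inside]))
        expect_equal(out$heart_rate[i], mean(act$heart_rate[inside]))
      }
    }
  }
})

test_that("sleep joins the closest preceding record within 28 h", {
  grid <- ts_utc("2023-03-07 12:00:00")
  sl <- function(end_offset_h, dur) {
    tibble::tibble(sleep_end = grid - end_offset_h * 3600,
                   sleep_duration = dur, deep_sleep_duration = dur / 4)
  }
  expect_equal(join_sleep(grid, sl(2, 8))$sleep_duration, 8)
  expect_true(is.na(join_sleep(grid, sl(30, 8))$sleep_duration))
  two <- dplyr::bind_rows(sl(20, 6), sl(6, 7.5))
  expect_equal(join_sleep(grid, two)$sleep_duration, 7.5)
  # boundary: exactly 28 h still joins
  expect_equal(join_sleep(grid, sl(28, 5))$sleep_duration, 5)
})

test_that("shrinking the sleep-join window never adds joined rows", {
  set.seed(11)
  grid <- ts_utc("2023-03-06 00:00:00") + sort(runif(60, 0, 6 * 86400))
  sleep <- tibble::tibble(
    sleep_end = ts_utc("2023-03-05 07:00:00") + sort(runif(5, 0, 5 * 86400)),
    sleep_duration = runif(5, 5, 9)
  )
  sleep$deep_sleep_duration <- sleep$sleep_duration / 4
  joined_wide <- !is.na(join_sleep(grid, sleep, 28)$sleep_duration)
  for (w in c(20, 12, 6)) {
    joined <- !is.na(join_sleep(grid, sleep, w)$sleep_duration)
    expect_true(all(joined_wide | !joined))
    joined_wide <- joined
  }
})

test_that("stretch selection enforces the 24-h minimum and >7-day retention", {
  # gap-free 14-day subject: one stretch, retained
  coh <- simulate_cohort(cohort_config(n_subjects = 1, n_days = 14, seed = 8))
  st <- select_stretches(build_aligned_frame(coh))
  expect_equal(nrow(st), 1L)
  expect_equal(st$hours, 14 * 24)

  # longest stretch 20 h: dropped entirely
  al20 <- toy_aligned(rep(5, 80))  # 20 h of 15-min rows
  st20 <- select_stretches(al20[, setdiff(names(al20), "stretch_id")])
  expect_equal(nrow(st20), 0L)
  expect_equal(attr(st20, "excluded_subjects"), "S01")

  # stretches totaling 6 days: subject dropped
  al6 <- toy_aligned(rep(5, 6 * 96))
  st6 <- select_stretches(al6[, setdiff(names(al6), "stretch_id")])
  expect_equal(nrow(st6), 0L)

  # exactly 7 days is not enough ("needed to exceed 7 days")
  al7 <- toy_aligned(rep(5, 7 * 96))
  expect_equal(nrow(select_stretches(al7[, setdiff(names(al7), "stretch_id")])), 0L)
  al8 <- toy_aligned(rep(5, 8 * 96))
  expect_equal(nrow(select_stretches(al8[, setdiff(names(al8), "stretch_id")])), 1L)
})

test_that("stretch selection equals a brute-force scan over flag runs", {
  set.seed(19)
  for (rep in 1:25) {
    n <- sample(100:2000, 1)
    flags <- runif(n) > 0.02
    al <- toy_aligned(rep(5, n))
    al$glucose_avail <- flags
    al$activity_avail <- runif(n) > 0.02
    ok <- al$glucose_avail & al$activity_avail
    st <- select_stretches(al[, setdiff(names(al), "stretch_id")],
                           min_total_days = 0)
    # brute force: every maximal contiguous run of ok
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    keep <- runs$values & runs$lengths >= 96
    expect_equal(nrow(st), sum(keep))
    if (sum(keep)) {
      expect_equal(st$start, al$timestamp[starts[keep]])
      expect_equal(st$n_rows, runs$lengths[keep])
    }
  }
})

test_that("glucose split holds out the last three days of available data", {
  al <- toy_aligned(rep(5, 10 * 96))
  sp <- split_glucose(al)
  expect_equal(sum(sp$split == "train"), 7 * 96)
  expect_equal(sum(sp$split == "test"), 3 * 96)
  expect_true(max(sp$timestamp[sp$split == "train"]) <
                min(sp$timestamp[sp$split == "test"]))

  al4 <- toy_aligned(rep(5, 4 * 96))
  sp4 <- split_glucose(al4)
  expect_equal(sum(sp4$split == "train"), 96)
  expect_equal(sum(sp4$split == "test"), 3 * 96)

  expect_warning(sp3 <- split_glucose(toy_aligned(rep(5, 3 * 96))),
                 "excluded")
  expect_true(all(is.na(sp3$split)))
})

test_that("meal-detection split takes days 1-4 for training, 5-7 for testing", {
  al <- toy_aligned(rep(5, 11 * 96))
  sp <- split_mealdetect(al)
  expect_equal(sum(sp$split == "train"), 4 * 96)
  expect_equal(sum(sp$split == "test"), 3 * 96)
  expect_equal(sum(sp$split == "unused"), 4 * 96)
  expect_true(max(sp$timestamp[sp$split == "train"]) <
                min(sp$timestamp[sp$split == "test"]))
  expect_true(max(sp$timestamp[sp$split == "test"]) <
                min(sp$timestamp[sp$split == "unused"]))

  sp7 <- split_mealdetect(toy_aligned(rep(5, 7 * 96)))
  expect_equal(sum(sp7$split == "train"), 4 * 96)
  expect_equal(sum(sp7$split == "test"), 3 * 96)
  expect_equal(sum(sp7$split == "unused"), 0)

  expect_warning(split_mealdetect(toy_aligned(rep(5, 6 * 96))), "excluded")
})

test_that("splits partition: no timestamp lands in both train and test", {
  coh <- inject_gaps(simulate_cohort(cohort_config(n_subjects = 3, n_days = 12,
                                                   seed = 29)))
  al <- build_aligned_frame(coh)
  st <- select_stretches(al)
  al <- add_stretch_ids(al, st)
  for (sp in list(split_glucose(al), split_mealdetect(al))) {
    key_tr <- paste(sp$subject_id, sp$timestamp)[!is.na(sp$split) & sp$split == "train"]
    key_te <- paste(sp$subject_id, sp$timestamp)[!is.na(sp$split) & sp$split == "test"]
    expect_length(intersect(key_tr, key_te), 0)
  }
})
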