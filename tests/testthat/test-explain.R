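# Shapley attributions (local accuracy, hand-computed cases, dummy and
# symmetry axioms, cross-check against the booster's own float32
# implementation), grouped importance, Q3+IQR peaks and peak-feature
# frequencies.

test_that("local accuracy holds on every row of a seeded fit", {
  tr <- toy_regression_bundle(n = 500, p = 6, seed = 11, nrounds = 60)
  ex <- compute_attributions(tr$bundle, tr$x)
  gap <- abs(ex$base_value + rowSums(ex$contributions) - ex$raw_prediction)
  expect_lt(max(gap), 1e-6)
  # and the raw prediction tracks the booster's own evaluation
  marg <- predict(tr$bundle, tr$x, type = "margin")
  expect_lt(max(abs(ex$raw_prediction - marg)), 2e-5)
})

test_that("attributions match the booster's built-in TreeSHAP within float32 noise", {
  withr::with_seed(12, {
    n <- 800; p <- 8
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    x[sample(length(x), 400)] <- NA  # exercise default directions
    y <- ifelse(is.na(x[, 1]), 0, x[, 1]) + rnorm(n, 0, 0.2)
  })
  b <- fit_model(x, y, "glucose_regression", nrounds = 50, seed = 12)
  ex <- compute_attributions(b, x)
  pc <- predict(b$booster, xgboost::xgb.DMatrix(data.matrix(x), nthread = 1),
                predcontrib = TRUE)
  expect_lt(max(abs(pc[, 1:p] - ex$contributions)), 2e-5)
  expect_lt(max(abs(pc[, p + 1] - ex$base_value)), 2e-5)
})

test_that("a constant model attributes nothing", {
  x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "f1"))
  b <- fit_model(x, rep(2.5, 50), "glucose_regression", nrounds = 3, seed = 1)
  ex <- compute_attributions(b, x)
  expect_true(all(abs(ex$contributions) < 1e-9))
  expect_equal(ex$base_value + rowSums(ex$contributions),
               ex$raw_prediction, tolerance = 1e-9)
})

test_that("a depth-1 stump splits credit as the two leaf deviations", {
  withr::with_seed(13, {
    x <- matrix(rep(c(0, 1), c(30, 70)), 100, 1, dimnames = list(NULL, "f1"))
    y <- ifelse(x[, 1] == 1, 2, -1) + rnorm(100, 0, 1e-6)
  })
  b <- fit_model(x, y, "glucose_regression",
                 params = list(max_depth = 1, eta = 1), nrounds = 1, seed = 13)
  ex <- compute_attributions(b, x)
  trees <- glucolens:::booster_trees(b$booster, b$features)
  tr <- trees[[1]]
  leaves <- which(tr$feature < 0)
  expect_length(leaves, 2)
  vals <- tr$value[leaves]
  covers <- tr$cover[leaves]
  ev <- sum(vals * covers) / sum(covers)
  # each row's contribution is its own leaf value minus the weighted mean
  leaf_of_row <- ifelse(x[, 1] < tr$split[1], vals[1], vals[2])
  expect_equal(unname(ex$contributions[, 1]), leaf_of_row - ev,
               tolerance = 1e-9)
})

test_that("features the model never splits on receive zero everywhere", {
  withr::with_seed(14, {
    x <- matrix(rnorm(300 * 3), 300, 3,
                dimnames = list(NULL, c("signal", "noise", "dummy")))
    x[, "dummy"] <- 7  # constant: cannot be split on
    y <- x[, "signal"] + rnorm(300, 0, 0.1)
  })
  b <- fit_model(x, y, "glucose_regression", nrounds = 30, seed = 14)
  ex <- compute_attributions(b, x)
  expect_true(all(ex$contributions[, "dummy"] == 0))
})

test_that("duplicating a feature preserves the pair's combined weight", {
  withr::with_seed(15, {
    n <- 600
    x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- 2 * x[, 1] + x[, 2] + rnorm(n, 0, 0.2)
  })
  b1 <- fit_model(x, y, "glucose_regression", nrounds = 40, seed = 15)
  w1 <- colMeans(abs(compute_attributions(b1, x)$contributions))
  x2 <- cbind(x, a2 = x[, "a"])
  b2 <- fit_model(x2, y, "glucose_regression", nrounds = 40, seed = 15)
  w2 <- colMeans(abs(compute_attributions(b2, x2)$contributions))
  expect_equal(unname(w2[["a"]] + w2[["a2"]]), unname(w1[["a"]]),
               tolerance = 0.05 * w1[["a"]])
})

test_that("importance weights are means of absolutes, grouped per the reporting scheme", {
  contrib <- matrix(0, 4, 3,
                    dimnames = list(NULL, c("kcal_carb_2h_sum",
                                            "acceleration_24h_sum",
                                            "sleep_duration")))
  contrib[, 1] <- c(0.3, -0.3, 0.3, -0.3)
  ex <- structure(list(contributions = contrib, base_value = 0,
                       raw_prediction = rowSums(contrib),
                       features = colnames(contrib),
                       task = "glucose_regression"),
                  class = "shap_explanation")
  rep_ <- overall_importance(ex)
  expect_equal(rep_$features$weight[rep_$features$feature == "kcal_carb_2h_sum"],
               0.3)  # mean of |x|, not |mean|
  expect_equal(rep_$groups$percent[rep_$groups$group == "nutrition short-term"],
               100)
  expect_equal(sum(rep_$groups$percent), 100, tolerance = 1e-9)
})

test_that("the feature-to-group map covers the model surface and rejects strangers", {
  grp <- feature_group(glucose_predictor_names())
  expect_equal(unname(grp[glucose_predictor_names() == "kcal_carb_3h_sum"]),
               "nutrition short-term")
  expect_equal(unname(grp[glucose_predictor_names() == "kcal_fat_8h_sum"]),
               "nutrition long-term")
  expect_equal(unname(grp[glucose_predictor_names() == "acceleration_30m_sum"]),
               "activity short-term")
  expect_equal(unname(grp[glucose_predictor_names() == "acceleration_24h_sum"]),
               "activity long-term")
  expect_equal(unname(grp[glucose_predictor_names() == "heart_rate_24h_mean"]),
               "cardiometabolic")
  expect_equal(unname(grp[glucose_predictor_names() == "energy_expenditure_30m_sum"]),
               "cardiometabolic")
  expect_equal(unname(grp[glucose_predictor_names() == "sleep_duration"]),
               "sleep")
  expect_equal(unname(feature_group("subj_S07")), "subject")
  expect_error(feature_group("mystery_feature"), "cannot map")
})

test_that("peak detection implements the Q3 + IQR rule with plateau-first maxima", {
  expect_equal(nrow(find_peaks_q3iqr(1:50)$peaks), 0)  # monotone: no peaks
  x <- c(5, 5, 5, 5, 5, 5, 5, 5, 9, 5, 5, 5)
  ps <- find_peaks_q3iqr(x)
  expect_equal(ps$subjects$threshold, 5)
  expect_equal(ps$peaks$index, 9)
  expect_equal(ps$peaks$value, 9)
  expect_equal(nrow(find_peaks_q3iqr(rep(4, 20))$peaks), 0)  # constant series
  # a plateau peak is indexed at its first sample
  xp <- c(1, 2, 8, 8, 8, 2, 1, 1, 1, 1, 1, 1)
  expect_equal(find_peaks_q3iqr(xp)$peaks$index, 3)
})

test_that("subjects need 10 peaks to enter peak reporting", {
  # 9 spikes -> excluded; 11 spikes -> retained
  mk <- function(k) {
    x <- rep(5, 40 * k)
    x[seq(5, by = 40, length.out = k)] <- 9
    x
  }
  ex9 <- find_peaks_q3iqr(mk(9))$subjects
  expect_true(ex9$excluded)
  ex11 <- find_peaks_q3iqr(mk(11))$subjects
  expect_false(ex11$excluded)
  expect_equal(ex11$n_peaks, 11)
})

test_that("peak detection matches the brute-force quartile + scan oracle", {
  set.seed(16)
  for (rep in 1:60) {
    n <- sample(10:200, 1)
    x <- round(exp(rnorm(n, log(5.5), 0.2)), sample(c(1, 2, 6), 1))
    got <- find_peaks_q3iqr(x, min_peaks = 1)
    want <- bf_peaks(x)
    expect_equal(got$subjects$threshold, want$threshold, tolerance = 1e-12)
    expect_equal(got$peaks$index, want$peaks)
  }
})

test_that("peak feature frequencies count the top-5 per peak and sum to 5 x n_peaks", {
  withr::with_seed(17, {
    n <- 400
    x <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("subj_S0", 1:8)))
    y <- 3 * x[, 1] + x[, 2] + rnorm(n, 0, 0.1)
  })
  b <- fit_model(x, y, "glucose_regression", nrounds = 30, seed = 17)
  ex <- compute_attributions(b, x)
  glu <- rep(5, n)
  spikes <- seq(10, 390, by = 10)
  glu[spikes] <- 9
  pk <- find_peaks_q3iqr(glu, rep("S01", n))
  freq <- peak_feature_frequency(ex, pk, k = 5)
  expect_equal(sum(freq$count), 5 * length(spikes))
  np <- attr(freq, "n_peaks")
  expect_equal(np$n_peaks, length(spikes))
  # a single dominant feature is always among the top entries
  top <- freq$feature[which.max(freq$count)]
  expect_equal(top, "subj_S01")
})

test_that("non-tree models are rejected", {
  fake <- structure(list(task = "glucose_regression", booster = lm(y ~ x,
                    data = data.frame(x = 1:5, y = 1:5)), features = "x"),
                    class = "model_bundle")
  expect_error(compute_attributions(fake, data.frame(x = 1)),
               "tree-ensemble")
})
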