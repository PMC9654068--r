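# Evaluation surface: pooled and per-subject classification metrics,
# per-subject MAE summaries on the mmol/L scale, and percentile Bland-Altman
# agreement.

#' Classification accuracy, sensitivity and specificity
#'
#' Thresholds predicted probabilities (default 0.5) and reports pooled
#' accuracy, sensitivity and specificity together with per-subject values
#' and their min-max range. Subjects without positives (or without
#' negatives) have an undefined sensitivity (specificity) and are excluded
#' from that metric's range with a warning.
#'
#' @param probabilities Predicted positive-class probabilities.
#' @param labels True 0/1 labels.
#' @param subject_id Parallel subject vector.
#' @param threshold Decision threshold on the probability.
#' @return A list: `overall` tibble (metric, value, min, max), `per_subject`
#'   tibble, `n_rows`, `n_subjects`.
#' @export
classification_metrics <- function(probabilities, labels, subject_id,
                                   threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels),
            length(labels) == length(subject_id))
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  pred <- as.integer(probabilities >= threshold)
  rates <- function(p, y) {
    tp <- sum(p == 1 & y == 1); tn <- sum(p == 0 & y == 0)
    fp <- sum(p == 1 & y == 0); fn <- sum(p == 0 & y == 1)
    c(accuracy = (tp + tn) / length(y),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }
  overall <- rates(pred, labels)
  per_subject <- lapply(split(seq_along(labels), subject_id), function(idx) {
    tibble::tibble(n = length(idx), !!!as.list(rates(pred[idx], labels[idx])))
  })
  per_subject <- dplyr::bind_rows(per_subject, .id = "subject_id")
  for (m in c("sensitivity", "specificity")) {
    und <- is.na(per_subject[[m]])
    if (any(und))
      warnf("%s undefined for subject(s) %s; excluded from the range", m,
            paste(per_subject$subject_id[und], collapse = ", "))
  }
  rng <- function(v) c(min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  overall_tbl <- tibble::tibble(
    metric = names(overall),
    value = unname(overall),
    min = vapply(names(overall), function(m) rng(per_subject[[m]])[["min"]],
                 numeric(1)),
    max = vapply(names(overall), function(m) rng(per_subject[[m]])[["max"]],
                 numeric(1))
  )
  list(overall = overall_tbl, per_subject = per_subject,
       n_rows = length(labels), n_subjects = dplyr::n_distinct(subject_id))
}

#' Per-subject mean absolute error summary
#'
#' MAE is computed per subject on the natural mmol/L scale (predictions are
#' expected already back-transformed) and summarized as the unweighted mean
#' and SD across subjects.
#'
#' @param predicted,observed Glucose in mmol/L.
#' @param subject_id Parallel subject vector.
#' @return A list: `per_subject` tibble (subject_id, n, mae), `mean`, `sd`.
#' @export
mae_summary <- function(predicted, observed, subject_id) {
  stopifnot(length(predicted) == length(observed),
            length(observed) == length(subject_id))
  if (any(observed <= 0, na.rm = TRUE)) stopf("observed glucose must be positive")
  per_subject <- tibble::tibble(
    subject_id = subject_id, err = abs(predicted - observed)
  ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n = dplyr::n(), mae = mean(.data$err), .groups = "drop")
  list(per_subject = per_subject,
       mean = mean(per_subject$mae),
       sd = sd(per_subject$mae))
}

#' Percentile Bland-Altman agreement
#'
#' Differences are `predicted - observed`; the bias is their mean and the
#' limits of agreement are the 2.5th and 97.5th type-7 percentiles of the
#' differences (not +/- 1.96 SD).
#'
#' @param predicted,observed Paired measurements (mmol/L).
#' @return A list: `bias`, `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  d <- predicted - observed
  d <- d[!is.na(d)]
  if (length(d) < 2) stopf("Bland-Altman needs at least 2 paired values")
  loa <- quantile(d, c(0.025, 0.975), type = 7, names = FALSE)
  list(bias = mean(d), loa_lower = loa[1], loa_upper = loa[2], n = length(d))
}
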