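# Optional diagnostic plots.

#' Bland-Altman plot with percentile limits of agreement
#'
#' @param predicted,observed Paired glucose values (mmol/L).
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(predicted, observed) {
  ba <- bland_altman(predicted, observed)
  df <- data.frame(mean = (predicted + observed) / 2,
                   diff = predicted - observed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of predicted and observed (mmol/L)",
                  y = "Predicted - observed (mmol/L)",
                  title = sprintf("Bias %.3f, LoA [%.2f, %.2f] mmol/L",
                                  ba$bias, ba$loa_lower, ba$loa_upper))
}

#' Goodness-of-fit trace for one subject
#'
#' @param timestamp POSIXct grid times.
#' @param observed,predicted Glucose (mmol/L).
#' @return A ggplot object.
#' @export
plot_glucose_fit <- function(timestamp, observed, predicted) {
  df <- data.frame(timestamp = rep(timestamp, 2),
                   glucose = c(observed, predicted),
                   series = rep(c("observed", "predicted"),
                                each = length(timestamp)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp, y = .data$glucose,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "Glucose (mmol/L)", colour = NULL)
}
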