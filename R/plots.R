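#' Plot a discriminability map
#'
#' Channels x time raster of signed r-squared values, diverging palette
#' centered at 0.
#'
#' @param object An `srsq_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.srsq_map <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                   fill = .data$srsq)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "time (ms)", y = NULL, fill = "sgn r²") +
    ggplot2::theme_minimal()
}

#' Plot target-centered error topography
#'
#' @param object An `error_topography` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.error_topography <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$d_col, .data$d_row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n), color = "grey80") +
    ggplot2::geom_text(data = df[df$n > 0, ], ggplot2::aes(label = .data$n),
                       size = 3) +
    ggplot2::scale_y_reverse(breaks = -5:5) +
    ggplot2::scale_x_continuous(breaks = -5:5) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = "column offset", y = "row offset", fill = "trials") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Accuracy and ITR curves over sequences
#'
#' Line plots of selection accuracy (and optionally ITR) against the number
#' of sequences, one line per paradigm; cohort tibbles are averaged over
#' subjects first.
#'
#' @param data An `accuracy` tibble from [run_speller_study()] /
#'   [simulate_subjects()] (columns `condition`, `n_sequences`, `accuracy`,
#'   optionally `subject`).
#' @param metric `"accuracy"` or `"itr"`.
#' @return A ggplot object.
#' @export
plot_accuracy_curves <- function(data, metric = c("accuracy", "itr")) {
  metric <- match.arg(metric)
  if ("subject" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$condition, .data$n_sequences) |>
      dplyr::summarise(dplyr::across(dplyr::any_of(c("accuracy", "itr")),
                                     mean), .groups = "drop")
  }
  ggplot2::ggplot(data, ggplot2::aes(.data$n_sequences, .data[[metric]],
                                     color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "number of sequences",
                  y = if (metric == "accuracy") "selection accuracy"
                      else "ITR (bits/min)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a TTI accuracy profile
#'
#' @param data A tibble from [tti_accuracy_profile()], optionally with a
#'   `condition` column for grouped profiles.
#' @return A ggplot object.
#' @export
plot_tti_profile <- function(data) {
  aes <- if ("condition" %in% names(data)) {
    ggplot2::aes(.data$tti_bin, .data$accuracy, group = .data$condition,
                 color = .data$condition)
  } else {
    ggplot2::aes(.data$tti_bin, .data$accuracy, group = 1)
  }
  ggplot2::ggplot(data[!is.na(data$accuracy), ], aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "non-targets preceding the target (TTI)",
                  y = "per-flash accuracy", color = NULL) +
    ggplot2::theme_minimal()
}
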