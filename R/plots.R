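#' Plot class-average ERPs of an epoch set
#'
#' @param object an [epoch_set()].
#' @param channels channel labels to show (default `c("Fz", "Cz", "Pz")`,
#'   intersected with what is present).
#' @param ... unused.
#' @return a ggplot object: one panel per channel, one line per class.
#' @export
autoplot.epoch_set <- function(object, channels = c("Fz", "Cz", "Pz"), ...) {
  channels <- intersect(channels, object$channel_labels)
  if (length(channels) == 0) channels <- object$channel_labels[1]
  df <- as_tibble(subset_epochs(object, channels = channels)) |>
    dplyr::group_by(.data$label, .data$time, .data$channel) |>
    dplyr::summarise(amplitude = mean(.data$amplitude), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$amplitude, colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(
      x = "time (s)", y = expression(amplitude ~ (mu * V)),
      colour = "workload"
    ) +
    ggplot2::theme_minimal()
}

#' Plot spatial patterns of a filter bank
#'
#' @param object a `filter_bank`.
#' @param ... unused.
#' @return a ggplot object: per-channel pattern weights, one panel per
#'   filter.
#' @export
autoplot.filter_bank <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = rownames(object$W))
  ggplot2::ggplot(df, ggplot2::aes(.data$channel, .data$pattern)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~filter, ncol = 1) +
    ggplot2::labs(x = NULL, y = "pattern weight (max-abs normalized)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot cross-validated accuracies
#'
#' @param object a `cv_result` or `workload_report`.
#' @param ... unused.
#' @return a ggplot object with per-fold accuracies, fold means, and the 50%
#'   chance line.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$chain, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05, height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "held-out accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cv_result
#' @export
autoplot.workload_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$chain, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$chance_threshold,
                        linetype = 3, colour = "firebrick") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05, height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "held-out accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
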