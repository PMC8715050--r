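# ggplot2 visualisations for traces, fits and condition effects.

#' Plot a gaze trace with detected saccades
#'
#' Time course of horizontal and vertical eye position with detected events
#' shaded.
#'
#' @param trace One trial's gaze tibble.
#' @param events Optional event tibble for the same trial.
#' @return A ggplot object.
#' @export
plot_gaze_trace <- function(trace, events = NULL) {
  long <- tidyr::pivot_longer(trace, c("x_deg", "y_deg"),
                              names_to = "axis", values_to = "position")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t_ms, .data$position,
                                          colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "eye position (deg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$onset_ms, xmax = .data$offset_ms),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40",
      inherit.aes = FALSE)
  }
  p
}

#' Plot a fitted main sequence
#'
#' Scatter of saccade amplitude against peak velocity with the fitted
#' hyperbolic curve.
#'
#' @param object A `main_sequence_fit`.
#' @param events The events the fit was computed from (for the scatter).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot main_sequence_fit
#' @export
autoplot.main_sequence_fit <- function(object, events = NULL, ...) {
  xr <- if (!is.null(events)) range(events$amplitude_deg) else c(0.5, 20)
  curve <- tibble::tibble(amplitude_deg = seq(xr[1], xr[2],
                                              length.out = 200))
  curve$peak_vel_deg_s <- predict(object, curve$amplitude_deg)
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$amplitude_deg,
                                           .data$peak_vel_deg_s))
  if (!is.null(events)) {
    p <- p + ggplot2::geom_point(data = events, alpha = 0.2, size = 0.6)
  }
  p + ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "amplitude (deg)", y = "peak velocity (deg/s)",
                  title = sprintf("alpha = %.0f deg/s, beta = %.3f /deg",
                                  object$alpha, object$beta)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot condition effects of an effort measure
#'
#' Per-subject condition means (thin lines) and cohort means (points) of a
#' measure across reward levels, faceted by display duration.
#'
#' @param summary A [summarize_conditions()] table.
#' @param measure One of its measure columns, e.g. `"frequency"`.
#' @return A ggplot object.
#' @export
plot_condition_effects <- function(summary, measure = "frequency") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(factor(.data$reward_cents),
                               .data[[measure]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                       alpha = 0.25) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          colour = "firebrick") +
    ggplot2::facet_wrap(~ .data$duration_condition) +
    ggplot2::labs(x = "reward (cents)", y = measure) +
    ggplot2::theme_minimal()
}
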