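#' Plot an insole recording
#'
#' Acceleration channels as lines with swing phases (pressure word at or
#' below the threshold, or the `swing` column if present) shaded.
#'
#' @param object An [insole_recording()] (a `swing` column, if present, is
#'   used for the shading; otherwise the raw threshold rule is applied).
#' @param threshold Pressure threshold used for shading when no `swing`
#'   column is present.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.insole_recording <- function(object, threshold = 1, ...) {
  df <- tibble::as_tibble(object)
  swing <- if ("swing" %in% names(df)) df$swing else
    as.integer(df$pressure <= threshold)
  long <- tidyr::pivot_longer(
    dplyr::mutate(df[c("t", "ax", "ay", "az")], swing = swing),
    cols = c("ax", "ay", "az"),
    names_to = "axis", values_to = "acceleration"
  )
  runs <- rle(swing)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  shade <- tibble::tibble(xmin = df$t[starts[runs$values == 1L]],
                          xmax = df$t[ends[runs$values == 1L]])
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$acceleration,
                                          colour = .data$axis))
  if (nrow(shade) > 0) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
      ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA,
      inherit.aes = FALSE
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(acceleration ~ (m/s^2)),
                  colour = "axis",
                  title = "Insole recording (shaded: swing phases)")
}

#' Plot a cumulative distance estimate
#'
#' Cumulative estimated distance as a step function of time, one step per
#' stride landing.
#'
#' @param object A `gait_distance` object from [estimate_distance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_distance <- function(object, ...) {
  df <- tidy(object)
  steps <- tibble::tibble(
    time = c(0, df$stop_time),
    distance = c(0, df$distance)
  )
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$distance)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(x = .data$stop_time, y = .data$distance)) +
    ggplot2::labs(x = "time (s)", y = "cumulative distance (m)",
                  title = sprintf("Estimated walking distance: %.2f m over %d strides",
                                  object$total_distance, object$stride_count))
}

#' Plot an evaluation result
#'
#' Per-walk distance estimates with the reference distance(s) overlaid.
#'
#' @param object A `gait_evaluation` object from [loocv_evaluate()] or
#'   [error_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_evaluation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$walk, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$reference_distance),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "walk", y = "estimated distance (m)",
                  title = sprintf("Held-out estimates (mean relative error %.2f%%)",
                                  100 * object$summary$error))
}
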