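#' Plot the two satisfaction curves
#'
#' Staff satisfaction against the service-time ratio and patient
#' satisfaction against the waiting-time ratio, on a shared dimensionless
#' axis.
#'
#' @param patient_params,staff_params Curve parameters.
#' @param from,to Ratio range to draw.
#' @return A ggplot object.
#' @export
plot_satisfaction_curves <- function(patient_params = eslqueue::patient_params(),
                                     staff_params = eslqueue::staff_params(),
                                     from = -1, to = 1) {
  ratio <- seq(from, to, length.out = 400)
  df <- dplyr::bind_rows(
    tibble::tibble(ratio = ratio, level = staff_satisfaction(ratio, staff_params),
                   curve = "staff vs service-time ratio"),
    tibble::tibble(ratio = ratio, level = patient_satisfaction(ratio, patient_params),
                   curve = "patient vs waiting-time ratio"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$level,
                                   colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time ratio (dimensionless)", y = "satisfaction level",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a staff satisfaction fit over its data
#'
#' @param object A `staff_fit` object.
#' @param points Optional data frame of the fitted `(delta_s, level)`
#'   points to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot staff_fit
#' @export
autoplot.staff_fit <- function(object, points = NULL, ...) {
  xr <- if (is.null(points)) c(-1, 1) else range(points$delta_s)
  grid <- seq(xr[1], xr[2], length.out = 400)
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(
      data = tibble::tibble(delta_s = grid,
                            level = staff_satisfaction(grid, object$params)),
      ggplot2::aes(x = .data$delta_s, y = .data$level), colour = "#2166ac",
      linewidth = 0.9)
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(x = .data$delta_s, y = .data$level),
      alpha = 0.25, size = 1)
  }
  p + ggplot2::labs(x = "service-time ratio", y = "satisfaction level",
                    title = "Fitted double-tanh staff satisfaction curve") +
    ggplot2::theme_minimal()
}

#' Plot a total satisfaction curve
#'
#' Patient, staff and total satisfaction against the waiting-time ratio,
#' with the effective satisfaction level marked. Larger ratios correspond
#' to shorter actual waits, so the service-time axis runs right-to-left.
#'
#' @param object An `esl_tsc` object from [sweep_tsc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot esl_tsc
#' @export
autoplot.esl_tsc <- function(object, ...) {
  long <- tidyr::pivot_longer(object$points,
                              c("patient_level", "staff_level", "tsl"),
                              names_to = "series", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta_p, y = .data$level,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::annotate("point", x = object$eop$delta_p, y = object$esl,
                      shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = "waiting-time ratio (larger = shorter wait)",
                  y = "satisfaction level", colour = NULL,
                  title = sprintf("Total satisfaction curve (ESL %.3f)",
                                  object$esl)) +
    ggplot2::theme_minimal()
}

#' Plot a scenario comparison
#'
#' One total satisfaction curve per expected waiting time.
#'
#' @param object An `esl_comparison` object from [scenario_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot esl_comparison
#' @export
autoplot.esl_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$delta_p, y = .data$tsl,
                               colour = factor(.data$expected_wait_h))) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_point(data = object$summary,
                        ggplot2::aes(x = .data$delta_p_at_eop, y = .data$esl,
                                     colour = factor(.data$expected_wait_h)),
                        shape = 4, size = 3, stroke = 1.2) +
    ggplot2::labs(x = "waiting-time ratio", y = "total satisfaction level",
                  colour = "expected wait (h)",
                  title = "Total satisfaction curves by patient expectation") +
    ggplot2::theme_minimal()
}
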