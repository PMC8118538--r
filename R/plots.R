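#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_contour
#'   geom_raster labs theme_minimal scale_fill_viridis_c
#' @export
ggplot2::autoplot

#' Plot a heat-source model fit over its data
#'
#' @param object An `eq1_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eq1_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- eq1_eval(object$params, object$window, d$time_s)
  ggplot(d, aes(x = .data$time_s)) +
    geom_point(aes(y = .data$temp_C), alpha = 0.4, size = 0.8) +
    geom_line(aes(y = .data$fitted), color = "firebrick") +
    labs(x = "time (s)", y = "temperature rise (°C)",
         title = sprintf("Heat-source fit: P0 = %.3g W", object$params$p0),
         subtitle = sprintf("alpha = %.3g °C/W/s, tau = %.3g s, RMSE %.2g °C",
                            object$params$alpha, object$params$tau, object$rmse)) +
    theme_minimal()
}

#' Plot a calibration-curve fit
#'
#' @param object A `beta_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$x), max(d$x), length.out = 100)
  pred <- if (object$model == "quadratic") object$beta * xs^2 else object$beta * xs
  if (object$intercept)
    pred <- pred + stats::coef(object$lm)[["(Intercept)"]]
  ggplot(d, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_line(data = tibble::tibble(x = xs, y = pred), color = "steelblue") +
    labs(x = object$x, y = "peak temperature rise (°C)",
         subtitle = sprintf("beta = %.3g, R² = %.3f",
                            object$beta, object$r_squared)) +
    theme_minimal()
}

#' Plot calibrated alpha(P) and tau(P) with their polynomial fits
#'
#' @param object A `calibration_set`.
#' @param ... Unused.
#' @return A ggplot (faceted over the two parameters).
#' @export
autoplot.calibration_set <- function(object, ...) {
  d <- tidyr::pivot_longer(object$fits, c("alpha", "tau"),
                           names_to = "param", values_to = "value")
  ps <- seq(object$power_range[1], object$power_range[2], length.out = 100)
  fitline <- dplyr::bind_rows(
    tibble::tibble(power = ps, param = "alpha",
                   value = polyval_asc(object$alpha_poly, ps)),
    tibble::tibble(power = ps, param = "tau",
                   value = polyval_asc(object$tau_poly, ps)))
  ggplot(d, aes(x = .data$power, y = .data$value)) +
    geom_point() +
    geom_line(data = fitline, color = "steelblue") +
    ggplot2::facet_wrap(~param, scales = "free_y") +
    labs(x = "power (W)", y = NULL,
         title = "Calibrated absorption coefficient and time constant") +
    theme_minimal()
}

#' Plot a predicted sequence temperature curve
#'
#' @param object A `sequence_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sequence_prediction <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$time_s, y = .data$temp_C)) +
    geom_line(color = "firebrick") +
    labs(x = "time (s)", y = "temperature rise (°C)",
         title = sprintf("%s%.3g W for %.0f s: predicted Tmax %.2f °C%s",
                         if (nzchar(object$label)) paste0(object$label, ": ") else "",
                         object$power, object$duration, object$tmax,
                         if (object$extrapolated) " (extrapolated)" else "")) +
    theme_minimal()
}

#' Isotherm contour chart of predicted peak temperature
#'
#' @param object An `isotherm_grid`.
#' @param breaks Isotherm levels, degC.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.isotherm_grid <- function(object, breaks = c(1, 2, 4, 6, 10, 15, 20), ...) {
  ggplot(object, aes(x = .data$duration, y = .data$power, z = .data$tmax)) +
    geom_raster(aes(fill = .data$tmax)) +
    geom_contour(breaks = breaks, color = "white") +
    scale_fill_viridis_c(name = "Tmax (°C)") +
    labs(x = "sequence duration (s)", y = "emitted power (W)",
         title = "Predicted maximal temperature rise") +
    theme_minimal()
}

#' Plot the temporal-sd (precision) map of a slice
#'
#' @param maps A `precision_maps` object.
#' @param slice Slice index.
#' @param which `"sigma"` or `"mu"`.
#' @return A ggplot.
#' @export
plot_precision_map <- function(maps, slice = 1L, which = c("sigma", "mu")) {
  which <- match.arg(which)
  m <- maps[[which]][slice, , ]
  d <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d$value <- m[cbind(d$row, d$col)]
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = sprintf("%s (°C)", which)) +
    labs(x = NULL, y = NULL,
         title = sprintf("%s map, slice %d",
                         if (which == "sigma") "Temporal SD" else "Temporal mean",
                         slice)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
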