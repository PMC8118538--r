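#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a heat-source model fit
#'
#' @param x An `eq1_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.eq1_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "tau"),
                 estimate = c(x$params$alpha, x$params$tau),
                 std.error = unname(x$se[c("alpha", "tau")]))
}

#' One-row summary of a heat-source model fit
#'
#' @param x An `eq1_fit`.
#' @param ... Unused.
#' @return A tibble with `p0`, `rmse`, `peak`, `low_signal`, `nobs`.
#' @export
glance.eq1_fit <- function(x, ...) {
  tibble::tibble(p0 = x$params$p0, rmse = x$rmse,
                 peak = eq1_peak(x$params, x$window),
                 low_signal = x$low_signal, nobs = nrow(x$data))
}

#' Tidy a calibration-curve fit
#'
#' @param x A `beta_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.beta_fit <- function(x, ...) {
  tibble::tibble(term = "beta", estimate = x$beta, std.error = x$se)
}

#' One-row summary of a calibration-curve fit
#'
#' @param x A `beta_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `r.squared`, `nobs`.
#' @export
glance.beta_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r_squared,
                 nobs = nrow(x$data))
}

#' Tidy a calibration set
#'
#' @param x A `calibration_set`.
#' @param ... Unused.
#' @return The per-power table: `power`, `alpha`, `tau`.
#' @export
tidy.calibration_set <- function(x, ...) x$fits

#' One-row summary of a calibration set
#'
#' @param x A `calibration_set`.
#' @param ... Unused.
#' @return A tibble with the polynomial coefficients (ascending) and the
#'   calibrated power range.
#' @export
glance.calibration_set <- function(x, ...) {
  tibble::tibble(
    alpha_c0 = x$alpha_poly[1], alpha_c1 = x$alpha_poly[2],
    alpha_c2 = x$alpha_poly[3],
    tau_c0 = x$tau_poly[1], tau_c1 = x$tau_poly[2], tau_c2 = x$tau_poly[3],
    power_min = x$power_range[1], power_max = x$power_range[2],
    n_powers = nrow(x$fits))
}
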