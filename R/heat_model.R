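#' Heating window
#'
#' Start and stop times (seconds) of constant-power energy deposition.
#'
#' @param t0,t1 Heating start and stop, s; `t1 > t0`.
#' @return A list of class `heating_window`.
#' @export
heating_window <- function(t0, t1) {
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0)
    stop_input("heating window requires t1 > t0.")
  structure(list(t0 = t0, t1 = t1), class = "heating_window")
}

#' Heat-source model parameters
#'
#' Parameters of the piecewise-logarithmic temperature response at the
#' hottest point of a Gaussian heat source driven at constant power:
#' `alpha` is the absorption coefficient (degC W^-1 s^-1) — how efficiently
#' emitted RF power converts to local heating — and `tau` is a time constant
#' (s) set by the source size and the medium's thermal diffusivity.
#'
#' @param alpha Absorption coefficient, degC W^-1 s^-1, >= 0.
#' @param tau Time constant, s, > 0.
#' @param p0 Applied constant power, W, >= 0.
#' @return A list of class `eq1_params`.
#' @export
eq1_params <- function(alpha, tau, p0) {
  if (!is.finite(tau) || tau <= 0)
    stop_input("`tau` must be positive.", class2 = "invalid-params")
  if (!is.finite(alpha) || alpha < 0) stop_input("`alpha` must be >= 0.")
  if (!is.finite(p0) || p0 < 0) stop_input("`p0` must be >= 0.")
  structure(list(alpha = alpha, tau = tau, p0 = p0), class = "eq1_params")
}

#' Evaluate the heat-source temperature model
#'
#' Temperature rise at the hottest point of an isotropic Gaussian heat
#' source driven at constant power `p0` between `t0` and `t1`:
#' zero before heating; `alpha p0 tau ln((t - t0 + tau)/tau)` during
#' heating; `alpha p0 tau ln((t - t0 + tau)/(t - t1 + tau))` during
#' cooling. Continuous at both switch points; tends to zero as
#' `t -> Inf`.
#'
#' @param params An [eq1_params()].
#' @param window A [heating_window()].
#' @param t Numeric vector of times, s.
#' @return Temperature rise, degrees C, same length as `t`.
#' @export
eq1_eval <- function(params, window, t) {
  a <- params$alpha * params$p0 * params$tau
  tau <- params$tau
  t0 <- window$t0; t1 <- window$t1
  out <- numeric(length(t))
  heat <- t > t0 & t <= t1
  cool <- t > t1
  out[heat] <- a * log((t[heat] - t0 + tau) / tau)
  out[cool] <- a * log((t[cool] - t0 + tau) / (t[cool] - t1 + tau))
  out
}

#' Peak temperature rise of the heat-source model
#'
#' The model is increasing during heating and decreasing afterwards, so the
#' maximum is reached exactly at `t1`:
#' `alpha p0 tau ln((t1 - t0 + tau)/tau)`.
#'
#' @inheritParams eq1_eval
#' @return Peak temperature rise, degrees C.
#' @export
eq1_peak <- function(params, window) {
  params$alpha * params$p0 * params$tau *
    log((window$t1 - window$t0 + params$tau) / params$tau)
}

#' Fit the heat-source model to a heating curve
#'
#' Nonlinear least squares over `(alpha, tau)` with `alpha >= 0`,
#' `tau > 0`, given the applied power and the heating window. Initialized
#' with `tau` at 10% of the heating duration and `alpha` solved from the
#' observed peak via the closed form; on non-convergence, restarts from 5
#' log-spaced `tau` values.
#'
#' @param curve A data frame with columns `time_s` and `temp_C` covering the
#'   heating phase and at least part of the cooling phase.
#' @param window A [heating_window()].
#' @param p0 Applied power, W (> 0).
#' @return An object of class `eq1_fit`: fitted [eq1_params()], standard
#'   errors, residual RMSE, a `low_signal` flag (set when the fitted
#'   absorption is within two standard errors of zero), and the data.
#'   Use [generics::tidy()] / [generics::glance()] on it.
#' @export
fit_eq1 <- function(curve, window, p0) {
  stopifnot(is.data.frame(curve), all(c("time_s", "temp_C") %in% names(curve)))
  if (!is.finite(p0) || p0 <= 0)
    stop_input("`p0` must be positive to identify alpha.")
  t <- curve$time_s; y <- curve$temp_C
  if (max(t) <= window$t1)
    stop_input("curve must extend past the end of heating.")
  dur <- window$t1 - window$t0
  tau0 <- 0.1 * dur
  near_end <- y[t > window$t1 - 5 & t <= window$t1 + 1]
  peak_obs <- if (length(near_end)) stats::median(near_end) else max(y)
  peak_obs <- max(peak_obs, 1e-3)
  model_fn <- function(alpha, tau)
    eq1_eval(list(alpha = alpha, tau = tau, p0 = p0), window, t)
  starts <- c(tau0, tau0 * 10^seq(-1, 1, length.out = 5))
  fit <- NULL
  for (ts in starts) {
    a0 <- peak_obs / (p0 * ts * log((dur + ts) / ts))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ model_fn(alpha, tau),
        start = list(alpha = a0, tau = ts),
        lower = c(alpha = 0, tau = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(alpha = NA_real_, tau = NA_real_))
  } else {
    # profile search: the model is linear in alpha given tau, so scan a tau
    # grid, solve alpha >= 0 in closed form, and keep the best pair. This is
    # the route taken by signal-free (all-noise) curves, where the gradient
    # in tau vanishes and the iterative fit cannot converge.
    taus <- exp(seq(log(0.01 * dur), log(2 * dur), length.out = 60))
    best <- NULL
    for (tau in taus) {
      g <- eq1_eval(list(alpha = 1, tau = tau, p0 = p0), window, t)
      den <- sum(g^2)
      if (den == 0) next
      alpha <- max(0, sum(g * y) / den)
      rss <- sum((y - alpha * g)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(alpha = alpha, tau = tau, rss = rss, den = den)
    }
    if (is.null(best))
      stop_fit("heat-source model fit failed to converge from all starts.",
               starts = starts, p0 = p0)
    sigma_hat <- sqrt(best$rss / max(1, length(y) - 2))
    est <- c(alpha = best$alpha, tau = best$tau)
    se <- c(alpha = sigma_hat / sqrt(best$den), tau = NA_real_)
  }
  resid <- y - model_fn(est["alpha"], est["tau"])
  structure(
    list(params = eq1_params(unname(max(est["alpha"], 0)), unname(est["tau"]), p0),
         se = c(alpha = unname(se["alpha"]), tau = unname(se["tau"])),
         rmse = sqrt(mean(resid^2)),
         low_signal = is.na(se["alpha"]) ||
           est["alpha"] < 2 * se["alpha"],
         window = window, data = tibble::as_tibble(curve), nls = fit),
    class = "eq1_fit")
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat(sprintf(
    "<eq1_fit> alpha = %.4g +/- %.2g degC/W/s, tau = %.4g +/- %.2g s | P0 = %.3g W, RMSE %.3g degC%s\n",
    x$params$alpha, x$se["alpha"], x$params$tau, x$se["tau"],
    x$params$p0, x$rmse, if (x$low_signal) " [low signal]" else ""))
  invisible(x)
}

#' Fit second-order polynomials alpha(P) and tau(P) across powers
#'
#' Ordinary least squares of the per-power absorption coefficients and time
#' constants on power, with a quadratic model; with exactly three distinct
#' powers the polynomial interpolates. The calibrated power range is stored
#' so downstream predictions can flag extrapolation.
#'
#' @param fits A data frame with columns `power`, `alpha`, `tau` (one row
#'   per calibration power), or a list of `eq1_fit` objects.
#' @return An object of class `calibration_set` with `alpha_poly` and
#'   `tau_poly` (coefficients, ascending powers: intercept, linear,
#'   quadratic), `power_range`, and the per-power table.
#' @export
fit_power_polynomials <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits) &&
      all(vapply(fits, inherits, logical(1), "eq1_fit"))) {
    fits <- purrr::map_dfr(fits, function(f)
      tibble::tibble(power = f$params$p0, alpha = f$params$alpha,
                     tau = f$params$tau))
  }
  stopifnot(is.data.frame(fits), all(c("power", "alpha", "tau") %in% names(fits)))
  if (length(unique(fits$power)) < 3)
    stop_input("need at least 3 distinct powers to fit quadratics.")
  fa <- stats::lm(alpha ~ power + I(power^2), data = fits)
  ft <- stats::lm(tau ~ power + I(power^2), data = fits)
  structure(
    list(alpha_poly = unname(stats::coef(fa)),
         tau_poly = unname(stats::coef(ft)),
         power_range = range(fits$power),
         fits = tibble::as_tibble(fits)),
    class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf(
    "<calibration_set> %d powers in [%.3g, %.3g] W\n  alpha(P) = %.4g + %.4g P + %.4g P^2\n  tau(P)   = %.4g + %.4g P + %.4g P^2\n",
    nrow(x$fits), x$power_range[1], x$power_range[2],
    x$alpha_poly[1], x$alpha_poly[2], x$alpha_poly[3],
    x$tau_poly[1], x$tau_poly[2], x$tau_poly[3]))
  invisible(x)
}

polyval_asc <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

#' A sequence abstracted to its emitted power and duration
#'
#' @param power Effective emitted power, W (total energy / duration).
#' @param duration Acquisition duration, s.
#' @param label Free-text name.
#' @return A one-row tibble of class `sequence_spec`.
#' @export
sequence_spec <- function(power, duration, label = "") {
  if (!is.finite(power) || power < 0) stop_input("`power` must be >= 0.")
  if (!is.finite(duration) || duration <= 0) stop_input("`duration` must be > 0.")
  out <- tibble::tibble(label = label, power = power, duration = duration)
  class(out) <- c("sequence_spec", class(out))
  out
}

#' Predict the temperature evolution and peak for an MRI sequence
#'
#' Evaluates the calibrated polynomials at the sequence's effective power to
#' obtain `alpha` and `tau`, then simulates the heat-source model with the
#' heating window `(0, duration)`. Refuses to predict (rather than clipping)
#' when the polynomials give a negative absorption coefficient or
#' non-positive time constant at that power; flags extrapolation outside the
#' calibrated power range.
#'
#' @param calib A `calibration_set` from [fit_power_polynomials()].
#' @param spec A [sequence_spec()] (or data frame with `power`, `duration`,
#'   optional `label`).
#' @param dt Sampling interval of the returned curve, s.
#' @param cool_factor Curve extends to `cool_factor * duration` to show the
#'   cooling phase.
#' @return A list of class `sequence_prediction`: `tmax` (degC), `alpha`,
#'   `tau`, `extrapolated` flag, and `curve` (tibble `time_s`, `temp_C`).
#' @export
predict_for_sequence <- function(calib, spec, dt = 1, cool_factor = 1.5) {
  stopifnot(inherits(calib, "calibration_set"))
  power <- spec$power[1]; duration <- spec$duration[1]
  label <- if ("label" %in% names(spec)) spec$label[1] else ""
  times <- seq(0, cool_factor * duration, by = dt)
  if (power == 0) {
    return(structure(list(
      label = label, power = power, duration = duration,
      alpha = 0, tau = NA_real_, tmax = 0, extrapolated = FALSE,
      curve = tibble::tibble(time_s = times, temp_C = 0)),
      class = "sequence_prediction"))
  }
  alpha <- polyval_asc(calib$alpha_poly, power)
  tau <- polyval_asc(calib$tau_poly, power)
  if (alpha < 0 || tau <= 0)
    stop_domain(sprintf(
      "calibration polynomials give alpha = %.3g, tau = %.3g at P = %.3g W; refusing to predict.",
      alpha, tau, power))
  extrap <- power < calib$power_range[1] || power > calib$power_range[2]
  params <- eq1_params(alpha, tau, power)
  window <- heating_window(0, duration)
  structure(list(
    label = label, power = power, duration = duration,
    alpha = alpha, tau = tau,
    tmax = eq1_peak(params, window),
    extrapolated = extrap,
    curve = tibble::tibble(time_s = times,
                           temp_C = eq1_eval(params, window, times))),
    class = "sequence_prediction")
}

#' @export
print.sequence_prediction <- function(x, ...) {
  cat(sprintf(
    "<sequence_prediction>%s P = %.3g W for %.0f s -> Tmax = %.2f degC%s\n",
    if (nzchar(x$label)) paste0(" ", x$label, ":") else "",
    x$power, x$duration, x$tmax,
    if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Isotherm grid of predicted peak temperature over power and duration
#'
#' Tabulates [predict_for_sequence()] peak values over a power x duration
#' grid. Cells where the calibration polynomials leave the physical domain
#' (negative alpha or tau) are returned as `NA` rather than clipped.
#'
#' @param calib A `calibration_set`.
#' @param powers Numeric vector, W.
#' @param durations Numeric vector, s.
#' @return A tibble of class `isotherm_grid` with columns `power`,
#'   `duration`, `tmax`, in long format (one row per grid cell).
#' @export
isotherm_grid <- function(calib, powers, durations) {
  stopifnot(inherits(calib, "calibration_set"))
  grid <- tidyr::expand_grid(power = powers, duration = durations)
  grid$tmax <- purrr::map2_dbl(grid$power, grid$duration, function(p, d) {
    tryCatch({
      if (p == 0) return(0)
      alpha <- polyval_asc(calib$alpha_poly, p)
      tau <- polyval_asc(calib$tau_poly, p)
      if (alpha < 0 || tau <= 0) return(NA_real_)
      eq1_peak(eq1_params(alpha, tau, p), heating_window(0, d))
    }, error = function(e) NA_real_)
  })
  class(grid) <- c("isotherm_grid", class(grid))
  grid
}

#' Fit a calibration curve of peak temperature against a sequence parameter
#'
#' Origin-constrained least squares of the end-of-heating maximal
#' temperature rise on a sequence parameter: `T = beta x^2` for flip angle
#' or B1+rms (heating power scales with the square of either), or
#' `T = beta x` for emitted energy. An unconstrained variant with intercept
#' is available but not the default.
#'
#' @param data A data frame.
#' @param x,y Column names (strings or bare names via `[[`) of the predictor
#'   and the peak temperature, degC.
#' @param model `"quadratic"` (`T = beta x^2`) or `"linear"` (`T = beta x`).
#' @param intercept Include an intercept term (default `FALSE`).
#' @return An object of class `beta_fit` with `beta`, `se`, `r_squared`,
#'   the `lm` fit and the data.
#' @export
fit_beta <- function(data, x, y = "tmax_C", model = c("quadratic", "linear"),
                     intercept = FALSE) {
  model <- match.arg(model)
  xv <- data[[x]]; yv <- data[[y]]
  if (length(xv) < 2) stop_input("need at least 2 points.")
  if (all(xv == 0)) stop_input("degenerate predictor: all values zero.")
  pred <- if (model == "quadratic") xv^2 else xv
  df <- data.frame(pred = pred, y = yv)
  fit <- if (intercept) stats::lm(y ~ pred, data = df)
  else stats::lm(y ~ pred - 1, data = df)
  sm <- summary(fit)
  beta <- unname(stats::coef(fit)[["pred"]])
  se <- sm$coefficients["pred", "Std. Error"]
  structure(list(beta = beta, se = se, r_squared = sm$r.squared,
                 model = model, intercept = intercept,
                 x = x, y = y, lm = fit,
                 data = tibble::tibble(x = xv, y = yv)),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("<beta_fit> T = %.4g * %s%s | se %.2g, R^2 %.3f\n",
              x$beta, x$x, if (x$model == "quadratic") "^2" else "",
              x$se, x$r_squared))
  invisible(x)
}

#' Naive energy-based estimate of peak temperature
#'
#' `Tmax = beta3 * E`: the linear calibration coefficient against total
#' emitted energy applied to another sequence's energy. Provided because it
#' is the obvious first guess from sequence bookkeeping — and because it is
#' inadequate near a wire, where the peak depends on how fast the energy is
#' delivered, not just on how much.
#'
#' @param beta3 Linear coefficient, degC/J (>= 0).
#' @param energy Total emitted energy, J (>= 0).
#' @return Estimated peak temperature rise, degC.
#' @export
energy_estimate <- function(beta3, energy) {
  beta3 * energy
}
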