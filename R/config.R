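#' Reconstruction configuration
#'
#' Settings of the PRFS temperature reconstruction. The PRFS coefficient is
#' the thermal sensitivity of the water proton resonance frequency,
#' -0.0094 ppm per degree C; together with the gyromagnetic ratio, field
#' strength and echo time it converts a phase difference to a temperature
#' change.
#'
#' @param prf_coeff PRFS thermal coefficient in ppm per degree C (negative).
#' @param gamma Proton gyromagnetic ratio in Hz/T.
#' @param n_reference Number of initial dynamics averaged into the phase
#'   reference.
#' @param heating_window_dynamics Length-2 integer vector: dynamic indices
#'   (1-based acquisition numbers) at which energy deposition starts and
#'   stops.
#' @param end_window Length-2 integer vector of dynamics over which the
#'   end-of-heating mean temperature is computed (inclusive).
#'
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(prf_coeff = -0.0094, gamma = 42.576e6,
                         n_reference = 10L,
                         heating_window_dynamics = c(10L, 90L),
                         end_window = c(86L, 90L)) {
  if (!is.finite(prf_coeff) || prf_coeff >= 0)
    stop_config("`prf_coeff` must be negative (ppm/degC).")
  if (n_reference < 1) stop_config("`n_reference` must be >= 1.")
  if (heating_window_dynamics[1] >= heating_window_dynamics[2])
    stop_config("heating window start must precede stop.")
  structure(list(prf_coeff = prf_coeff, gamma = gamma,
                 n_reference = as.integer(n_reference),
                 heating_window_dynamics = as.integer(heating_window_dynamics),
                 end_window = as.integer(end_window)),
            class = "recon_config")
}

#' Rad-per-degree conversion factor of a reconstruction configuration
#'
#' Returns the (negative) factor k such that delta_phi = k * delta_T, i.e.
#' k = 2 pi * gamma * B0 * c_PRF * TE with c_PRF in absolute units.
#'
#' @param cfg A `recon_config`.
#' @param te Echo time, s.
#' @param b0 Field strength, T.
#' @return Scalar, radians per degree C.
#' @export
prfs_rad_per_degc <- function(cfg, te, b0) {
  if (!is.finite(te) || te <= 0) stop_config("`te` must be positive.", field = "te")
  if (!is.finite(b0) || b0 <= 0) stop_config("`b0` must be positive.", field = "b0")
  2 * pi * cfg$gamma * b0 * (cfg$prf_coeff * 1e-6) * te
}

#' Temporal low-pass filter configuration
#'
#' Causal Butterworth filter applied pixel-by-pixel along dynamics. The
#' default (first order, 0.04 Hz cutoff at 1 Hz sampling) introduces a
#' latency of about three repetition times, compensated downstream by
#' `lag_samples`.
#'
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param order Filter order (>= 1).
#' @param sampling_hz Sampling rate (dynamics per second).
#' @param lag_samples Latency in samples to compensate when comparing
#'   filtered curves to unfiltered references.
#'
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cutoff_hz = 0.04, order = 1L, sampling_hz = 1.0,
                          lag_samples = 3L) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= sampling_hz / 2)
    stop_config("`cutoff_hz` must lie in (0, sampling_hz/2).")
  if (order < 1) stop_config("`order` must be >= 1.")
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 sampling_hz = sampling_hz,
                 lag_samples = as.integer(lag_samples)),
            class = "filter_config")
}

#' Drift-correction configuration
#'
#' Per-dynamic background phase-drift model: a spatial polynomial (default
#' order 0, i.e. a scalar offset per slice) fit over a background mask that
#' excludes the heated region, temporally smoothed with a trailing moving
#' average.
#'
#' @param window Trailing temporal window, in dynamics, over which the
#'   per-dynamic drift estimates are averaged.
#' @param spatial_order Order of the in-plane polynomial background model
#'   (0 = constant offset).
#' @param background_mask Logical array `[slice, row, col]` (or matrix
#'   `[row, col]` recycled over slices) marking background pixels.
#'
#' @return A list of class `drift_config`.
#' @export
drift_config <- function(window = 10L, spatial_order = 0L,
                         background_mask = NULL) {
  if (window < 1) stop_config("`window` must be >= 1.")
  if (spatial_order < 0) stop_config("`spatial_order` must be >= 0.")
  structure(list(window = as.integer(window),
                 spatial_order = as.integer(spatial_order),
                 background_mask = background_mask),
            class = "drift_config")
}
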