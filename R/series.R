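#' @importFrom rlang abort
NULL

stop_input <- function(msg, ...) abort(msg, class = "wiretherm_input_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "wiretherm_config_error", ...)
stop_fit <- function(msg, ...) abort(msg, class = "wiretherm_fit_error", ...)
stop_domain <- function(msg, ...) abort(msg, class = "wiretherm_domain_error", ...)

#' Dynamic complex image series
#'
#' Container for a dynamic multi-slice complex-valued acquisition, the raw
#' input of the thermometry pipeline. Data are indexed
#' `[dynamic, slice, row, col]`; dynamics are assumed uniformly spaced in
#' time (one per TR).
#'
#' @param data Complex 4-D array `[dynamic, slice, row, col]`.
#' @param times Numeric vector of acquisition times in seconds, one per
#'   dynamic, uniformly spaced.
#' @param pixel_spacing In-plane pixel spacing in mm, length 2 `(row, col)`.
#' @param te Echo time in seconds.
#' @param b0 Static field strength in tesla.
#' @param tr Repetition time in seconds.
#' @param slice_spacing Center-to-center slice spacing in mm.
#'
#' @return An object of class `complex_series`.
#' @export
complex_series <- function(data, times, pixel_spacing, te, b0, tr,
                           slice_spacing = 2.4) {
  if (!is.complex(data) || length(dim(data)) != 4L)
    stop_input("`data` must be a complex 4-D array [dynamic, slice, row, col].")
  if (length(times) != dim(data)[1])
    stop_input("`times` must have one entry per dynamic.")
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
      stop_input("`times` must be uniformly spaced.")
  }
  if (is.null(te) || !is.finite(te) || te <= 0)
    stop_input("`te` (echo time, s) must be positive.", field = "te")
  if (is.null(b0) || !is.finite(b0) || b0 <= 0)
    stop_input("`b0` (field strength, T) must be positive.", field = "b0")
  if (is.null(tr) || !is.finite(tr) || tr <= 0)
    stop_input("`tr` (repetition time, s) must be positive.", field = "tr")
  structure(
    list(data = data, times = as.numeric(times),
         pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
         te = te, b0 = b0, tr = tr, slice_spacing = slice_spacing),
    class = "complex_series")
}

#' @export
print.complex_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<complex_series> %d dynamics x %d slices x %dx%d px | TE %.1f ms, TR %.0f ms, B0 %.1f T\n",
    d[1], d[2], d[3], d[4], x$te * 1e3, x$tr * 1e3, x$b0))
  invisible(x)
}

#' Temperature-change image series
#'
#' Per-pixel temperature change (degrees C above baseline) over dynamics,
#' with processing provenance.
#'
#' @param dT Numeric 4-D array `[dynamic, slice, row, col]` of temperature
#'   change in degrees C.
#' @param times Seconds per dynamic.
#' @param pixel_spacing mm, length 2.
#' @param drift_corrected,filtered Provenance flags.
#' @param lag_samples Integer filter latency in dynamics (0 when unfiltered).
#' @param slice_spacing mm between slice centers.
#'
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(dT, times, pixel_spacing,
                               drift_corrected = FALSE, filtered = FALSE,
                               lag_samples = 0L, slice_spacing = 2.4) {
  if (length(dim(dT)) != 4L)
    stop_input("`dT` must be a 4-D array [dynamic, slice, row, col].")
  if (length(times) != dim(dT)[1])
    stop_input("`times` must have one entry per dynamic.")
  if (!all(is.finite(dT)))
    stop_input("`dT` must be finite everywhere.")
  structure(
    list(dT = dT, times = as.numeric(times),
         pixel_spacing = rep_len(as.numeric(pixel_spacing), 2L),
         drift_corrected = isTRUE(drift_corrected),
         filtered = isTRUE(filtered),
         lag_samples = as.integer(lag_samples),
         slice_spacing = slice_spacing),
    class = "temperature_series")
}

#' @export
print.temperature_series <- function(x, ...) {
  d <- dim(x$dT)
  cat(sprintf(
    "<temperature_series> %d dynamics x %d slices x %dx%d px | drift_corrected=%s filtered=%s lag=%d\n",
    d[1], d[2], d[3], d[4], x$drift_corrected, x$filtered, x$lag_samples))
  invisible(x)
}

#' Extract one pixel's temperature trajectory as a tibble
#'
#' @param dT A `temperature_series`.
#' @param pixel Integer vector `(slice, row, col)`.
#' @return A tibble with columns `time_s`, `temp_C`.
#' @export
pixel_curve <- function(dT, pixel) {
  stopifnot(inherits(dT, "temperature_series"), length(pixel) == 3L)
  tibble::tibble(time_s = dT$times,
                 temp_C = dT$dT[, pixel[1], pixel[2], pixel[3]])
}
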