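#' Build the reference phase image
#'
#' Averages the first `n_reference` dynamics of a complex series in the
#' complex domain and returns the argument of the mean. Complex averaging is
#' robust at the +/- pi wrap, where an arithmetic mean of phases is not.
#'
#' @param series A [complex_series()].
#' @param n_reference Number of initial dynamics to average.
#' @return Numeric array `[slice, row, col]` of reference phase in
#'   `(-pi, pi]` radians.
#' @export
build_reference <- function(series, n_reference = 10L) {
  stopifnot(inherits(series, "complex_series"))
  nd <- dim(series$data)[1]
  if (n_reference > nd)
    stop_input(sprintf("n_reference (%d) exceeds available dynamics (%d).",
                       n_reference, nd))
  ref <- apply(series$data[seq_len(n_reference), , , , drop = FALSE],
               c(2, 3, 4), mean)
  Arg(ref)
}

#' Convert a wrapped phase difference to temperature change
#'
#' PRFS conversion: `dT = delta_phi / (2 pi gamma B0 c_PRF TE)` with the
#' PRFS coefficient in absolute (ppm x 1e-6) units. Linear in `delta_phi`;
#' the coefficient is negative, so heating lowers the phase at positive TE.
#'
#' @param delta_phi Phase difference to the reference, radians, wrapped to
#'   `(-pi, pi]`. Any numeric array.
#' @param te Echo time, s.
#' @param b0 Field strength, T.
#' @param cfg A [recon_config()].
#' @return Temperature change, degrees C, same shape as `delta_phi`.
#' @export
phase_to_temperature <- function(delta_phi, te, b0, cfg = recon_config()) {
  delta_phi / prfs_rad_per_degc(cfg, te, b0)
}

#' Reconstruct a temperature series from a complex series
#'
#' Builds the reference phase from the first `cfg$n_reference` dynamics,
#' takes the temporal phase difference of every dynamic to that reference,
#' wraps it to `(-pi, pi]` (no spatial unwrapping; heating is tracked
#' incrementally), and converts to temperature change via the PRFS relation.
#'
#' @param series A [complex_series()].
#' @param cfg A [recon_config()].
#' @return A [temperature_series()] (not drift corrected, not filtered).
#' @export
reconstruct_temperature <- function(series, cfg = recon_config()) {
  ref <- build_reference(series, cfg$n_reference)
  d <- dim(series$data)
  # wrapped difference via the complex plane: Arg(z * conj(e^{i ref}))
  conj_ref <- exp(-1i * ref)
  dphi <- array(0, d)
  for (t in seq_len(d[1]))
    dphi[t, , , ] <- Arg(array(series$data[t, , , , drop = FALSE], d[2:4]) * conj_ref)
  dT <- phase_to_temperature(dphi, series$te, series$b0, cfg)
  temperature_series(dT, series$times, series$pixel_spacing,
                     slice_spacing = series$slice_spacing)
}

# ---- drift correction -------------------------------------------------------

poly_design <- function(rows, cols, order) {
  # orthonormal-ish design on normalized coordinates, all terms up to `order`
  r <- (rows - mean(rows)) / max(1, diff(range(rows)) / 2)
  c_ <- (cols - mean(cols)) / max(1, diff(range(cols)) / 2)
  terms <- list(rep(1, length(rows)))
  if (order >= 1) {
    for (i in seq_len(order)) for (j in 0:i) {
      terms[[length(terms) + 1L]] <- r^(i - j) * c_^j
    }
  }
  do.call(cbind, terms)
}

#' Correct background phase drift in a temperature series
#'
#' For each dynamic and slice, fits a spatial polynomial of order
#' `cfg$spatial_order` to the temperature over the background mask, smooths
#' the fitted fields with a trailing moving average over the last
#' `cfg$window` dynamics, and subtracts the smoothed background estimate
#' from every pixel. After correction the background mean is approximately
#' zero at every dynamic; a drift-free series passes through unchanged.
#'
#' @param dT A [temperature_series()].
#' @param cfg A [drift_config()] whose `background_mask` excludes the heated
#'   region.
#' @return A [temperature_series()] with `drift_corrected = TRUE`.
#' @export
correct_drift <- function(dT, cfg = drift_config()) {
  stopifnot(inherits(dT, "temperature_series"))
  d <- dim(dT$dT)
  mask <- cfg$background_mask
  if (is.null(mask)) stop_input("drift correction requires a background mask.")
  if (is.matrix(mask)) {
    mask <- aperm(array(mask, c(d[3], d[4], d[2])), c(3, 1, 2))
  }
  if (!any(mask)) stop_input("background mask is empty.")
  nd <- d[1]; ns <- d[2]
  # raw per-dynamic background fields [dyn, slice, row, col]
  bg <- array(0, d)
  rows <- as.vector(row(matrix(0, d[3], d[4])))
  cols <- as.vector(col(matrix(0, d[3], d[4])))
  X <- poly_design(rows, cols, cfg$spatial_order)
  for (s in seq_len(ns)) {
    m <- as.vector(mask[s, , ])
    if (!any(m)) stop_input(sprintf("background mask empty in slice %d.", s))
    Xm <- X[m, , drop = FALSE]
    # pseudo-inverse once per slice; LS fit of each dynamic's background
    XtXinv <- solve(crossprod(Xm))
    H <- XtXinv %*% t(Xm)
    for (t in seq_len(nd)) {
      y <- as.vector(dT$dT[t, s, , ])[m]
      beta <- H %*% y
      bg[t, s, , ] <- X %*% beta
    }
  }
  # trailing moving average over the last `window` dynamics
  sm <- bg
  w <- cfg$window
  if (w > 1) {
    cs <- apply(bg, c(2, 3, 4), cumsum)   # [dyn, slice, row, col]
    for (t in seq_len(nd)) {
      lo <- max(1L, t - w + 1L)
      n <- t - lo + 1L
      sm[t, , , ] <- (cs[t, , , ] - (if (lo > 1) cs[lo - 1L, , , ] else 0)) / n
    }
  }
  out <- dT
  out$dT <- dT$dT - sm
  out$drift_corrected <- TRUE
  out
}

# ---- temporal low-pass filter ----------------------------------------------

butter_coefs <- function(cfg) {
  W <- cfg$cutoff_hz / (cfg$sampling_hz / 2)
  bt <- signal::butter(cfg$order, W, type = "low")
  list(b = bt$b, a = bt$a)
}

# steady-state initial state of the direct-form-II-transposed recursion,
# per unit input, so a constant series passes with no start-up transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1L) return(numeric(0))
  A <- rbind(-a[-1], cbind(diag(1, n - 2L, n - 2L),
                           rep(0, max(0L, n - 2L))))
  A <- A[seq_len(n - 1L), seq_len(n - 1L), drop = FALSE]
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(1, n - 1L) - t(A), B))
}

# causal IIR along rows of x (time) for all columns (pixels) at once
iir_apply <- function(b, a, x, zi_unit) {
  x <- as.matrix(x)
  nt <- nrow(x); np <- ncol(x)
  nz <- length(zi_unit)
  y <- matrix(0, nt, np)
  z <- outer(zi_unit, x[1, ])        # state matched to first sample
  if (nz == 0L) return(x * b[1])
  for (t in seq_len(nt)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    for (k in seq_len(nz)) {
      znext <- if (k < nz) z[k + 1L, ] else 0
      z[k, ] <- b[k + 1L] * xt + znext - a[k + 1L] * yt
    }
    y[t, ] <- yt
  }
  y
}

#' Apply the causal temporal low-pass filter pixel by pixel
#'
#' Single-pass (causal) Butterworth filter along dynamics, with internal
#' state initialized to steady state at the first sample so a constant
#' series passes through exactly. DC gain is exactly 1. A causal filter is
#' used — not zero-phase forward-backward filtering — because the method it
#' implements runs in real time; the resulting latency is compensated by
#' `lag_samples` (default 3 dynamics).
#'
#' @param dT A [temperature_series()].
#' @param cfg A [filter_config()].
#' @return A [temperature_series()] with `filtered = TRUE` and
#'   `lag_samples` set from `cfg`.
#' @export
lowpass_filter <- function(dT, cfg = filter_config()) {
  stopifnot(inherits(dT, "temperature_series"))
  d <- dim(dT$dT)
  if (d[1] < 10) stop_input("series too short for filter warm-up (need >= 10 dynamics).")
  co <- butter_coefs(cfg)
  zi <- lfilter_zi(co$b, co$a)
  x <- matrix(dT$dT, nrow = d[1])
  y <- iir_apply(co$b, co$a, x, zi)
  out <- dT
  out$dT <- array(y, d)
  out$filtered <- TRUE
  out$lag_samples <- cfg$lag_samples
  out
}

#' Filter a single temperature curve
#'
#' Convenience wrapper around the same causal filter for 1-D curves
#' (e.g. hottest-pixel trajectories).
#'
#' @param x Numeric vector sampled at `cfg$sampling_hz`.
#' @param cfg A [filter_config()].
#' @return Numeric vector, filtered.
#' @export
lowpass_filter_curve <- function(x, cfg = filter_config()) {
  if (length(x) < 10) stop_input("curve too short for filter warm-up.")
  co <- butter_coefs(cfg)
  as.numeric(iir_apply(co$b, co$a, matrix(x, ncol = 1), lfilter_zi(co$b, co$a)))
}

# ---- statistics -------------------------------------------------------------

#' Per-pixel temporal mean and standard deviation maps
#'
#' @param dT A [temperature_series()].
#' @return A list of class `precision_maps` with arrays `mu` and `sigma`
#'   `[slice, row, col]`, both in degrees C.
#' @export
precision_maps <- function(dT) {
  stopifnot(inherits(dT, "temperature_series"))
  d <- dim(dT$dT)
  if (d[1] < 2) stop_input("precision maps need at least 2 dynamics.")
  x <- matrix(dT$dT, nrow = d[1])
  mu <- colMeans(x)
  sigma <- sqrt(colSums(sweep(x, 2, mu)^2) / (d[1] - 1))
  structure(list(mu = array(mu, d[2:4]), sigma = array(sigma, d[2:4])),
            class = "precision_maps")
}

#' Five-number box-plot summary of a map over a region of interest
#'
#' Lower value, first quartile, median, third quartile and 95th percentile
#' of the map restricted to the ROI, using the linear-interpolation quantile
#' convention (type 7).
#'
#' @param map Numeric array (any shape), e.g. a temporal-sd map.
#' @param roi Logical array of the same shape; must select at least one
#'   pixel.
#' @return A one-row tibble with columns `lower`, `q1`, `median`, `q3`,
#'   `p95`.
#' @export
roi_box_stats <- function(map, roi) {
  if (!identical(dim(map), dim(roi)) && length(map) != length(roi))
    stop_input("`map` and `roi` must have the same shape.")
  v <- map[as.logical(roi)]
  if (length(v) == 0) stop_input("ROI is empty.")
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  tibble::tibble(lower = q[1], q1 = q[2], median = q[3], q3 = q[4], p95 = q[5])
}

#' RMSE between two curves after lag compensation
#'
#' Advances `mr_curve` by `lag` samples (shifts it left), aligns it with
#' `probe_curve`, and returns the root-mean-square of the residual over the
#' overlapping region. Used to compare a filtered (hence delayed) MR
#' temperature curve with a reference probe curve.
#'
#' @param mr_curve,probe_curve Numeric vectors at the same sampling rate.
#' @param lag Non-negative integer, samples.
#' @return RMSE, degrees C.
#' @export
rmse_with_lag <- function(mr_curve, probe_curve, lag = 3L) {
  n <- min(length(mr_curve), length(probe_curve))
  if (lag < 0) stop_input("`lag` must be >= 0.")
  if (lag >= n) stop_input("`lag` must be smaller than the series length.")
  a <- mr_curve[(1 + lag):n]
  b <- probe_curve[1:(n - lag)]
  sqrt(mean((a - b)^2))
}

#' Locate the hottest pixel at the end of energy deposition
#'
#' Finds the pixel maximizing the mean temperature change over the
#' end-of-heating window (default dynamics 86 to 90 inclusive) and reports
#' that mean with its temporal standard deviation over the same window.
#' Ties break to the first pixel in `[slice, row, col]` order.
#'
#' @param dT A [temperature_series()].
#' @param end_window Length-2 integer vector of dynamic indices (inclusive).
#' @return A list with `pixel` (integer `(slice, row, col)`), `tmax`
#'   (mean over the window, degC), `tmax_sd` (temporal sd over the window),
#'   and `curve` (the pixel's full trajectory as a tibble).
#' @export
hottest_pixel <- function(dT, end_window = c(86L, 90L)) {
  stopifnot(inherits(dT, "temperature_series"))
  d <- dim(dT$dT)
  w <- seq.int(end_window[1], end_window[2])
  if (length(w) < 1 || end_window[1] < 1 || end_window[2] > d[1])
    stop_input("`end_window` must lie within the series.")
  x <- matrix(dT$dT[w, , , , drop = FALSE], nrow = length(w))
  m <- colMeans(x)
  idx <- which.max(m)                      # first max in column-major order
  arr_idx <- arrayInd(idx, d[2:4])
  px <- as.integer(arr_idx[1, ])
  sdv <- if (length(w) > 1) stats::sd(x[, idx]) else 0
  list(pixel = px, tmax = m[idx], tmax_sd = sdv,
       curve = pixel_curve(dT, px))
}

#' Full width at half maximum of a hotspot profile
#'
#' Takes the 1-D profile through `center` of a 2-D temperature map (along
#' the row of the hotspot by default), finds the half-maximum crossings by
#' linear interpolation, and returns the width in mm.
#'
#' @param map Numeric matrix `[row, col]`, degrees C.
#' @param center Integer `(row, col)` of the hotspot.
#' @param pixel_spacing mm per pixel along the profile.
#' @param axis `"col"` (profile along the hotspot's row, default) or
#'   `"row"`.
#' @return Width in mm.
#' @export
fwhm_profile <- function(map, center, pixel_spacing, axis = c("col", "row")) {
  axis <- match.arg(axis)
  v <- if (axis == "col") map[center[1], ] else map[, center[2]]
  pk_i <- which.max(v)
  pk <- v[pk_i]
  if (!is.finite(pk) || pk <= 0 || all(v == v[1]))
    abort("profile has no positive peak.",
          class = c("wiretherm_nopeak_error", "wiretherm_input_error"))
  half <- pk / 2
  cross <- function(idx_seq) {
    # walk away from the peak until the profile falls below half-maximum
    prev <- pk_i
    for (i in idx_seq) {
      if (v[i] <= half) {
        # linear interpolation between (prev, v[prev]) and (i, v[i])
        frac <- (v[prev] - half) / (v[prev] - v[i])
        return(abs(i - prev) * frac + abs(prev - pk_i))
      }
      prev <- i
    }
    abs(idx_seq[length(idx_seq)] - pk_i)  # never crosses: width to the edge
  }
  left <- if (pk_i > 1) cross((pk_i - 1):1) else 0
  right <- if (pk_i < length(v)) cross((pk_i + 1):length(v)) else 0
  spacing <- if (length(pixel_spacing) == 2)
    (if (axis == "col") pixel_spacing[2] else pixel_spacing[1])
  else pixel_spacing[1]
  (left + right) * spacing
}
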