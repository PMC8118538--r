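default_background_mask <- function(dims, end_maps, frac = 0.25) {
  # background = pixels below the `frac` quantile of end-of-heating |dT|;
  # excludes the hotspot without requiring a manual ROI
  thr <- stats::quantile(abs(end_maps), frac, type = 7)
  mask <- abs(end_maps) <= thr
  if (!any(mask)) mask[] <- TRUE
  mask
}

#' Reconstruct temperature maps and precision statistics from files
#'
#' End-to-end offline reconstruction: reads a magnitude/phase NIfTI pair
#' with its JSON sidecar, reconstructs the PRFS temperature series, applies
#' drift correction (order-0 background model over an automatic or supplied
#' mask) and the causal temporal low-pass filter, and writes the unfiltered
#' and filtered series, the per-pixel temporal mean/sd maps, the
#' hottest-pixel curve and a JSON summary into `out_dir`.
#'
#' @param mag_path,phase_path,meta_path Input files, see
#'   [read_complex_series()].
#' @param out_dir Output directory (created if needed).
#' @param cfg A [recon_config()].
#' @param fcfg A [filter_config()].
#' @param dcfg A [drift_config()]; when its `background_mask` is `NULL`, a
#'   mask excluding the hottest quartile (by end-of-heating temperature) is
#'   built automatically.
#' @param drift_correct Apply drift correction (default `TRUE`).
#' @return Invisibly, a list with the summary (also written as JSON) and
#'   output paths.
#' @export
run_reconstruct <- function(mag_path, phase_path, meta_path, out_dir,
                            cfg = recon_config(), fcfg = filter_config(),
                            dcfg = drift_config(), drift_correct = TRUE) {
  series <- read_complex_series(mag_path, phase_path, meta_path)
  dT <- reconstruct_temperature(series, cfg)
  d <- dim(dT$dT)
  ew <- pmin(cfg$end_window, d[1])
  if (drift_correct) {
    if (is.null(dcfg$background_mask)) {
      end_map <- apply(dT$dT[seq.int(ew[1], ew[2]), , , , drop = FALSE],
                       c(2, 3, 4), mean)
      dcfg$background_mask <- default_background_mask(d[2:4], end_map)
    }
    dT <- correct_drift(dT, dcfg)
  }
  dT_filt <- lowpass_filter(dT, fcfg)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    unfiltered = file.path(out_dir, "temperature_unfiltered.nii.gz"),
    filtered = file.path(out_dir, "temperature_filtered.nii.gz"),
    mu = file.path(out_dir, "mu_map.nii.gz"),
    sigma_unfiltered = file.path(out_dir, "sigma_map_unfiltered.nii.gz"),
    sigma_filtered = file.path(out_dir, "sigma_map_filtered.nii.gz"),
    curve = file.path(out_dir, "hottest_pixel_curve.csv"),
    summary = file.path(out_dir, "summary.json"))

  write_temperature_nifti(dT, paths$unfiltered)
  write_temperature_nifti(dT_filt, paths$filtered)
  pm <- precision_maps(dT)
  pm_f <- precision_maps(dT_filt)
  write_temperature_nifti(pm$mu, paths$mu, dT$pixel_spacing, dT$slice_spacing)
  write_temperature_nifti(pm$sigma, paths$sigma_unfiltered,
                          dT$pixel_spacing, dT$slice_spacing)
  write_temperature_nifti(pm_f$sigma, paths$sigma_filtered,
                          dT$pixel_spacing, dT$slice_spacing)

  hp <- hottest_pixel(dT, ew)
  hp_f <- hottest_pixel(dT_filt, ew)
  curve <- dplyr::mutate(hp$curve,
                         temp_C_filtered = hp_f$curve$temp_C[
                           match(.data$time_s, hp_f$curve$time_s)])
  utils::write.csv(curve, paths$curve, row.names = FALSE)

  summary <- list(
    n_dynamics = d[1], n_slices = d[2], matrix = d[3:4],
    drift_corrected = dT$drift_corrected,
    hottest_pixel = hp$pixel,
    tmax_unfiltered_C = hp$tmax, tmax_unfiltered_sd_C = hp$tmax_sd,
    tmax_filtered_C = hp_f$tmax, tmax_filtered_sd_C = hp_f$tmax_sd,
    sigma_mean_unfiltered_C = mean(pm$sigma),
    sigma_mean_filtered_C = mean(pm_f$sigma),
    lag_samples = dT_filt$lag_samples)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, paths = paths,
                 unfiltered = dT, filtered = dT_filt))
}

#' Calibrate the heating model from curves and/or a calibration table
#'
#' Two inputs are supported, separately or together. A long-format curve
#' table (`power`, `time_s`, `temp_C`) is fit per power with the
#' heat-source model and the resulting `alpha(P)`, `tau(P)` quadratics are
#' stored as a calibration set (JSON). A summary calibration table
#' (`fa_deg`, `b1rms_uT`, `energy_J`, `tmax_C`) yields the beta
#' coefficients: peak temperature against flip angle (quadratic), against
#' B1+rms (quadratic) and against emitted energy (linear).
#'
#' @param curves Data frame of heating curves, or a CSV path, or `NULL`.
#' @param table Summary calibration table (data frame or CSV path), or
#'   `NULL`.
#' @param out_dir Output directory.
#' @param window A [heating_window()] of the energy deposition.
#' @param heating_duration_s Used to convert `energy_J` to power when
#'   fitting betas' companion power column.
#' @return Invisibly, a list with `calibration` (a `calibration_set` or
#'   `NULL`), `betas` (tibble or `NULL`), per-power fit table, and output
#'   paths. At least 3 curve fits must succeed when `curves` is given.
#' @export
run_calibrate <- function(curves = NULL, table = NULL, out_dir,
                          window = heating_window(10, 90),
                          heating_duration_s = 80) {
  if (is.null(curves) && is.null(table))
    stop_input("provide heating curves and/or a calibration table.")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(paths = list())

  if (!is.null(curves)) {
    if (is.character(curves)) curves <- tibble::as_tibble(utils::read.csv(curves))
    stopifnot(all(c("power", "time_s", "temp_C") %in% names(curves)))
    powers <- sort(unique(curves$power))
    fits <- list(); failed <- character()
    for (p in powers) {
      if (p <= 0) next  # zero-power control curve carries no heating signal
      cv <- dplyr::filter(curves, .data$power == p)
      f <- tryCatch(fit_eq1(cv, window, p), error = function(e) e)
      if (inherits(f, "error")) failed <- c(failed, sprintf("P=%g: %s", p, conditionMessage(f)))
      else fits[[length(fits) + 1L]] <- f
    }
    if (length(fits) < 3)
      stop_fit(sprintf("only %d of %d curves could be fit; need >= 3.",
                       length(fits), length(powers)), failures = failed)
    if (length(failed))
      warning("unfittable curves: ", paste(failed, collapse = "; "))
    calib <- fit_power_polynomials(fits)
    out$calibration <- calib
    out$fit_table <- purrr::map_dfr(fits, function(f)
      dplyr::bind_cols(glance(f),
                       tidyr::pivot_wider(tidy(f),
                                          names_from = "term",
                                          values_from = c("estimate", "std.error"))))
    out$paths$calibration <- file.path(out_dir, "calibration.json")
    write_calibration_json(calib, out$paths$calibration)
    out$paths$fits <- file.path(out_dir, "eq1_fits.csv")
    utils::write.csv(out$fit_table, out$paths$fits, row.names = FALSE)
  }

  if (!is.null(table)) {
    if (is.character(table)) table <- load_calibration_table(table)
    b1 <- fit_beta(table, "fa_deg", "tmax_C", model = "quadratic")
    b2 <- fit_beta(table, "b1rms_uT", "tmax_C", model = "quadratic")
    b3 <- fit_beta(table, "energy_J", "tmax_C", model = "linear")
    out$betas <- tibble::tibble(
      coefficient = c("beta1", "beta2", "beta3"),
      predictor = c("fa_deg", "b1rms_uT", "energy_J"),
      model = c("quadratic", "quadratic", "linear"),
      estimate = c(b1$beta, b2$beta, b3$beta),
      std.error = c(b1$se, b2$se, b3$se),
      r.squared = c(b1$r_squared, b2$r_squared, b3$r_squared))
    out$beta_fits <- list(beta1 = b1, beta2 = b2, beta3 = b3)
    out$paths$betas <- file.path(out_dir, "beta_report.csv")
    utils::write.csv(out$betas, out$paths$betas, row.names = FALSE)
  }
  invisible(out)
}

#' Predict peak temperature rise for a list of sequences
#'
#' Loads a calibration set, predicts the temperature curve and peak for
#' each sequence from its effective power and duration, and tabulates an
#' isotherm grid over the calibrated power range. Sequences whose power
#' falls where the calibration polynomials turn nonphysical are reported as
#' not predictable rather than failing the run.
#'
#' @param calib A `calibration_set` or a path to its JSON.
#' @param sequences A data frame with columns `power`, `duration` and
#'   optionally `label`.
#' @param out_dir Output directory.
#' @param grid_powers,grid_durations Axes of the isotherm grid; defaults
#'   span the calibrated power range and up to twice the longest sequence.
#' @return Invisibly, a list with `predictions` (tibble), `curves`,
#'   `grid` (isotherm tibble) and output paths.
#' @export
run_predict <- function(calib, sequences, out_dir,
                        grid_powers = NULL, grid_durations = NULL) {
  if (is.character(calib)) calib <- read_calibration_json(calib)
  stopifnot(inherits(calib, "calibration_set"), is.data.frame(sequences))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!"label" %in% names(sequences))
    sequences$label <- sprintf("seq%d", seq_len(nrow(sequences)))
  preds <- purrr::map(seq_len(nrow(sequences)), function(i) {
    tryCatch(predict_for_sequence(calib, sequences[i, ]),
             wiretherm_domain_error = function(e) e)
  })
  pred_tbl <- purrr::map2_dfr(preds, seq_len(nrow(sequences)), function(p, i) {
    if (inherits(p, "error"))
      tibble::tibble(label = sequences$label[i], power = sequences$power[i],
                     duration = sequences$duration[i], tmax_C = NA_real_,
                     extrapolated = NA, note = "not predictable")
    else tibble::tibble(label = p$label, power = p$power,
                        duration = p$duration, tmax_C = p$tmax,
                        extrapolated = p$extrapolated, note = "")
  })
  if (any(pred_tbl$note == "not predictable"))
    warning("some sequences are outside the model domain: ",
            paste(pred_tbl$label[pred_tbl$note != ""], collapse = ", "))
  curves <- purrr::map_dfr(purrr::keep(preds, ~ !inherits(.x, "error")),
                           function(p) dplyr::mutate(p$curve, label = p$label))
  if (is.null(grid_powers))
    grid_powers <- seq(calib$power_range[1], calib$power_range[2],
                       length.out = 25)
  if (is.null(grid_durations))
    grid_durations <- seq(5, max(2 * max(sequences$duration), 10),
                          length.out = 25)
  grid <- isotherm_grid(calib, grid_powers, grid_durations)
  paths <- list(predictions = file.path(out_dir, "predictions.csv"),
                curves = file.path(out_dir, "predicted_curves.csv"),
                grid = file.path(out_dir, "isotherm_grid.csv"))
  utils::write.csv(pred_tbl, paths$predictions, row.names = FALSE)
  utils::write.csv(curves, paths$curves, row.names = FALSE)
  utils::write.csv(grid, paths$grid, row.names = FALSE)
  invisible(list(predictions = pred_tbl, curves = curves, grid = grid,
                 paths = paths))
}

#' Simulate a synthetic acquisition to files
#'
#' Generates a ground-truth heating experiment (Gaussian hotspot following
#' the heat-source model), its complex image series and a co-located probe
#' log, and writes them in the formats [run_reconstruct()] reads, together
#' with the truth for closed-loop testing.
#'
#' @param out_dir Output directory.
#' @param phantom A [phantom_spec()].
#' @param params An [eq1_params()].
#' @param window A [heating_window()].
#' @param times Acquisition times, s.
#' @param noise A [noise_drift_spec()].
#' @param te,b0,tr Acquisition metadata.
#' @param probe_sigma Probe sensor noise sd, degC.
#' @return Invisibly, list with the truth record and output paths.
#' @export
run_simulate <- function(out_dir, phantom = phantom_spec(),
                         params = eq1_params(0.05, 8, 20),
                         window = heating_window(10, 90), times = 0:119,
                         noise = noise_drift_spec(),
                         te = 0.018, b0 = 1.5, tr = 1.0,
                         probe_sigma = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_temperature_field(phantom, params, window, times)
  series <- simulate_complex_series(truth, recon_config(), noise, te, b0, tr)
  paths <- as.list(write_complex_series(series, out_dir))
  probe <- simulate_probe(truth, probe_sigma = probe_sigma,
                          seed = noise$seed + 1L)
  paths$probe <- file.path(out_dir, "probe_log.csv")
  utils::write.csv(probe, paths$probe, row.names = FALSE)
  paths$truth_curve <- file.path(out_dir, "truth_center_curve.csv")
  utils::write.csv(truth$center_curve, paths$truth_curve, row.names = FALSE)
  invisible(list(truth = truth, series = series, paths = paths))
}
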