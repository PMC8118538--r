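as_nifti_order <- function(arr4d) aperm(arr4d, c(3, 4, 2, 1))   # -> [row,col,slice,dyn]
from_nifti_order <- function(arr4d) aperm(arr4d, c(4, 3, 1, 2)) # -> [dyn,slice,row,col]

#' Write a complex series as magnitude + phase NIfTI with a JSON sidecar
#'
#' @param series A [complex_series()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths (magnitude, phase, metadata).
#' @export
write_complex_series <- function(series, dir, prefix = "series") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mag_path <- file.path(dir, paste0(prefix, "_mag.nii.gz"))
  phs_path <- file.path(dir, paste0(prefix, "_phase.nii.gz"))
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  pd <- c(series$pixel_spacing, series$slice_spacing, series$tr)
  RNifti::writeNifti(RNifti::asNifti(as_nifti_order(Mod(series$data)),
                                     pixdim = pd), mag_path)
  RNifti::writeNifti(RNifti::asNifti(as_nifti_order(Arg(series$data)),
                                     pixdim = pd), phs_path)
  jsonlite::write_json(
    list(te_s = series$te, tr_s = series$tr, b0_t = series$b0,
         pixel_spacing_mm = series$pixel_spacing,
         slice_spacing_mm = series$slice_spacing,
         times_s = series$times),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(magnitude = mag_path, phase = phs_path, metadata = meta_path))
}

#' Read a complex series from magnitude + phase NIfTI and a JSON sidecar
#'
#' Phase must be stored in radians.
#'
#' @param mag_path,phase_path 4-D NIfTI paths (x, y, slice, dynamic).
#' @param meta_path JSON sidecar with `te_s`, `tr_s`, `b0_t`,
#'   `pixel_spacing_mm` (and optionally `slice_spacing_mm`, `times_s`).
#' @return A [complex_series()].
#' @export
read_complex_series <- function(mag_path, phase_path, meta_path) {
  for (p in c(mag_path, phase_path, meta_path))
    if (!file.exists(p)) stop_input(sprintf("input file not found: %s", p))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("te_s", "tr_s", "b0_t"))
    if (is.null(meta[[f]]))
      stop_input(sprintf("metadata is missing required field '%s'.", f),
                 field = f)
  mag <- from_nifti_order(array(as.numeric(RNifti::readNifti(mag_path)),
                                dim = dim(RNifti::readNifti(mag_path))))
  phs <- from_nifti_order(array(as.numeric(RNifti::readNifti(phase_path)),
                                dim = dim(RNifti::readNifti(phase_path))))
  times <- meta$times_s
  if (is.null(times)) times <- (seq_len(dim(mag)[1]) - 1) * meta$tr_s
  complex_series(complex(real = mag * cos(phs), imaginary = mag * sin(phs)) |>
                   array(dim = dim(mag)),
                 times = times,
                 pixel_spacing = meta$pixel_spacing_mm,
                 te = meta$te_s, b0 = meta$b0_t, tr = meta$tr_s,
                 slice_spacing = meta$slice_spacing_mm %||% 2.4)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a temperature series (or map) as NIfTI
#'
#' @param x A [temperature_series()] or a 3-D array `[slice, row, col]`.
#' @param path Output `.nii.gz` path.
#' @param pixel_spacing,slice_spacing,tr Geometry, used when `x` is a bare
#'   array.
#' @return Invisibly, `path`.
#' @export
write_temperature_nifti <- function(x, path, pixel_spacing = c(0.8, 0.8),
                                    slice_spacing = 2.4, tr = 1.0) {
  if (inherits(x, "temperature_series")) {
    arr <- as_nifti_order(x$dT)
    pd <- c(x$pixel_spacing, x$slice_spacing, 1)
  } else {
    arr <- aperm(x, c(2, 3, 1))
    pd <- c(pixel_spacing, slice_spacing)
  }
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = pd), path)
  invisible(path)
}

#' Read a probe temperature log
#'
#' Two-column delimited text `(time_s, temp_C)`; the header row is optional
#' and the delimiter (whitespace, comma, tab, semicolon) is detected.
#'
#' @param path File path.
#' @return A tibble with columns `time_s`, `temp_C`.
#' @export
read_probe_log <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("probe log not found: %s", path))
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else if (grepl(";", first)) ";"
         else if (grepl("\t", first)) "\t" else ""
  tokens <- strsplit(trimws(first), if (sep == "") "\\s+" else sep)[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(tokens))))
  df <- utils::read.table(path, header = header, sep = sep,
                          strip.white = TRUE)
  if (ncol(df) < 2) stop_input("probe log must have two columns (time, temperature).")
  tibble::tibble(time_s = as.numeric(df[[1]]), temp_C = as.numeric(df[[2]]))
}

#' Load a calibration table
#'
#' Reads a CSV with columns `fa_deg`, `b1rms_uT`, `energy_J`, `tmax_C` (and
#' optionally `tmax_sd_C`). With no argument, loads the packaged example
#' table: ten measurements near a copper wire in agar gel at 1.5 T, heating
#' module flip angle 0-90 degrees in 10-degree steps, 80 s of heating.
#'
#' @param path CSV path; default is the packaged table.
#' @return A tibble.
#' @export
load_calibration_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "wire_calibration.csv",
                        package = "wiretherm", mustWork = TRUE)
  if (!file.exists(path)) stop_input(sprintf("calibration table not found: %s", path))
  df <- tibble::as_tibble(utils::read.csv(path))
  need <- c("fa_deg", "b1rms_uT", "energy_J", "tmax_C")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_input(sprintf("calibration table is missing column(s): %s",
                       paste(missing, collapse = ", ")))
  df
}

#' Serialize a calibration set to JSON
#'
#' Stores the per-power fits, the alpha/tau polynomial coefficients
#' (ascending) and the calibrated power range.
#'
#' @param calib A `calibration_set`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_calibration_json <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_set"))
  jsonlite::write_json(
    list(alpha_poly = calib$alpha_poly, tau_poly = calib$tau_poly,
         power_range = calib$power_range,
         fits = calib$fits),
    path, auto_unbox = FALSE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a calibration set from JSON
#'
#' @param path JSON path written by [write_calibration_json()].
#' @return A `calibration_set`.
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("calibration JSON not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(alpha_poly = as.numeric(j$alpha_poly),
                 tau_poly = as.numeric(j$tau_poly),
                 power_range = as.numeric(j$power_range),
                 fits = tibble::as_tibble(j$fits)),
            class = "calibration_set")
}
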