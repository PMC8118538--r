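#' Heating-module configuration
#'
#' An adjustable train of off-resonance RF pulses interleaved between
#' imaging blocks to deposit controlled RF energy. Deposited power scales
#' with the square of the pulse flip angle.
#'
#' @param fa_hm Flip angle of the heating-module pulses, degrees, in
#'   `[0, 180]`.
#' @param pulse_duration Pulse duration, s.
#' @param inter_pulse_delay Delay between consecutive pulses, s.
#' @param n_pulses Pulses per TR.
#' @return A list of class `heating_module_config`.
#' @export
heating_module_config <- function(fa_hm, pulse_duration = 1e-3,
                                  inter_pulse_delay = 2e-3, n_pulses = 242L) {
  if (fa_hm < 0 || fa_hm > 180) stop_input("`fa_hm` must be in [0, 180] degrees.")
  if (n_pulses > 0 && (pulse_duration <= 0 || inter_pulse_delay <= 0))
    stop_input("pulse timing must be positive when pulses are played.")
  structure(list(fa_hm = fa_hm, pulse_duration = pulse_duration,
                 inter_pulse_delay = inter_pulse_delay,
                 n_pulses = as.integer(n_pulses)),
            class = "heating_module_config")
}

#' Protocol timing
#'
#' @param tr Repetition time, s.
#' @param n_slices Slices imaged per TR.
#' @param slice_time Imaging time per slice (including fat saturation), s.
#' @return A list of class `protocol_timing`.
#' @export
protocol_timing <- function(tr = 1.0, n_slices = 3L, slice_time = 62e-3) {
  if (n_slices * slice_time > tr)
    stop_input("imaging alone exceeds the TR.")
  structure(list(tr = tr, n_slices = as.integer(n_slices),
                 slice_time = slice_time),
            class = "protocol_timing")
}

#' Duty cycle of the heating module per TR
#'
#' Fraction of each TR occupied by the pulse train:
#' `(n * pulse + (n - 1) * gap) / tr` — n pulse durations but only n - 1
#' inter-pulse gaps, which reproduces the 72% print-out for the default
#' 242 x (1 ms pulse, 2 ms gap) train in a 1 s TR (724 ms / 1000 ms).
#'
#' @param hm A [heating_module_config()].
#' @param timing A [protocol_timing()].
#' @return Duty cycle as a fraction of TR in `[0, 1]`.
#' @export
duty_cycle <- function(hm, timing) {
  n <- hm$n_pulses
  if (n == 0L) return(0)
  module <- n * hm$pulse_duration + (n - 1L) * hm$inter_pulse_delay
  if (module + timing$n_slices * timing$slice_time > timing$tr)
    stop_input(sprintf(
      "heating module (%.0f ms) plus imaging (%.0f ms) exceeds TR (%.0f ms).",
      module * 1e3, timing$n_slices * timing$slice_time * 1e3, timing$tr * 1e3),
      class2 = "timing-overflow")
  module / timing$tr
}

#' Energy reference model
#'
#' Scales the heating-module energy with the square of the flip angle from
#' a single reference measurement (fixed pulse shape, so energy is
#' proportional to FA^2).
#'
#' @param ref_fa Reference flip angle, degrees (> 0).
#' @param ref_energy Heating-module energy at `ref_fa` over the full heating
#'   period, J.
#' @return A list of class `energy_model`.
#' @export
energy_model <- function(ref_fa = 90, ref_energy = 12185) {
  if (ref_fa <= 0) stop_input("`ref_fa` must be positive.")
  if (ref_energy < 0) stop_input("`ref_energy` must be >= 0.")
  structure(list(ref_fa = ref_fa, ref_energy = ref_energy),
            class = "energy_model")
}

#' Heating-module energy at a flip angle
#'
#' `E(fa) = ref_energy * (fa / ref_fa)^2`. With `table = TRUE` the value is
#' truncated to whole joules, matching how scanner consoles print the
#' energy read-out.
#'
#' @param model An [energy_model()].
#' @param fa Flip angle, degrees (>= 0), vectorized.
#' @param table Truncate to whole joules for table output.
#' @return Energy, J.
#' @export
scale_energy <- function(model, fa, table = FALSE) {
  if (any(fa < 0)) stop_input("`fa` must be >= 0.")
  e <- model$ref_energy * (fa / model$ref_fa)^2
  if (table) floor(e) else e
}

#' B1+rms combination model
#'
#' Combines the constant imaging baseline with the FA-proportional
#' heating-module contribution in quadrature (root-sum-square of
#' independent RF power contributions):
#' `B(fa) = sqrt(baseline^2 + ((fa/ref_fa) * sqrt(ref_total^2 - baseline^2))^2)`.
#' This models the scanner's reported value; measured read-outs carry
#' rounding noise of about 0.1 uT.
#'
#' @param baseline Imaging-only B1+rms, uT.
#' @param ref_fa Reference flip angle, degrees.
#' @param ref_total Combined B1+rms at `ref_fa`, uT (>= baseline).
#' @return A list of class `b1_model`.
#' @export
b1_model <- function(baseline = 0.6, ref_fa = 90, ref_total = 4.1) {
  if (baseline < 0 || ref_total < baseline)
    stop_input("need `ref_total` >= `baseline` >= 0.")
  structure(list(baseline = baseline, ref_fa = ref_fa, ref_total = ref_total),
            class = "b1_model")
}

#' Combined B1+rms at a flip angle
#'
#' @param model A [b1_model()].
#' @param fa Flip angle, degrees (>= 0), vectorized.
#' @return B1+rms, uT.
#' @export
b1rms_combined <- function(model, fa) {
  if (any(fa < 0)) stop_input("`fa` must be >= 0.")
  hm_ref <- sqrt(model$ref_total^2 - model$baseline^2)
  sqrt(model$baseline^2 + ((fa / model$ref_fa) * hm_ref)^2)
}

#' Effective emitted power of a sequence
#'
#' Total emitted energy divided by acquisition duration.
#'
#' @param energy Total energy, J.
#' @param duration Acquisition duration, s (> 0).
#' @return Power, W.
#' @export
effective_power <- function(energy, duration) {
  if (any(duration <= 0)) stop_input("`duration` must be positive.")
  energy / duration
}

#' Total emitted energy from power and duration
#'
#' Exact inverse of [effective_power()].
#'
#' @param power Effective power, W.
#' @param duration Duration, s (> 0).
#' @return Energy, J.
#' @export
sequence_energy <- function(power, duration) {
  if (any(duration <= 0)) stop_input("`duration` must be positive.")
  power * duration
}
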