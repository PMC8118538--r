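# wiretherm

Rapid proton-resonance-frequency-shift (PRFS) MR thermometry near implanted
conductive wires, and a semi-empirical model that predicts the maximal
RF-induced temperature rise of any MRI sequence from its emitted power and
duration.

## The problem

RF pulses of an MRI sequence can induce currents along an implanted wire
(pacemaker lead, deep-brain-stimulation electrode, interventional guidewire)
and produce a local hotspot of several tens of degrees at the tip —
quantities like SAR or B₁⁺rms alone do not predict that peak, because it
depends on *how fast* the energy is delivered, not just on how much.
`wiretherm` implements the processing side of a calibration-based safety
assessment:

1. **Thermometry reconstruction.** Dynamic complex (magnitude + phase) EPI
   image series are converted to temperature-change maps with the PRFS
   method, ΔT = Δφ / (2π·γ·B₀·c·TE) with c = −0.0094 ppm/°C. The first 10
   dynamics form a complex-averaged phase reference; background phase drift
   is removed with a spatial-polynomial model smoothed over a trailing
   10-dynamic window; a causal first-order Butterworth filter (0.04 Hz
   cutoff) reduces the per-pixel temporal noise from ≈0.65 °C to ≈0.21 °C
   at a 3-sample latency.

2. **Heating model.** The temperature at the hottest pixel of a Gaussian
   heat source driven at constant power P₀ between t₀ and t₁ follows

       T(t) = 0                                   for t ≤ t₀
       T(t) = α·P₀·τ·ln((t − t₀ + τ)/τ)           for t₀ ≤ t ≤ t₁
       T(t) = α·P₀·τ·ln((t − t₀ + τ)/(t − t₁ + τ)) for t ≥ t₁

   where α (°C·W⁻¹·s⁻¹) is the absorption coefficient and τ (s) a thermal
   time constant. `fit_eq1()` recovers (α, τ) from each calibration heating
   curve; `fit_power_polynomials()` expresses α(P) and τ(P) as quadratics in
   power; `predict_for_sequence()` then gives the full temperature curve and
   peak for any sequence's (power, duration), and `isotherm_grid()` tabulates
   safety charts.

3. **Sequence bookkeeping.** FA²-scaling of heating-module energy,
   quadrature combination of imaging and heating B₁⁺rms contributions, the
   heating-module duty cycle per TR, and effective emitted power
   (energy/duration).

4. **Synthetic acquisitions.** A generator producing complex image series
   (Gaussian hotspot following the model above, background phase drift,
   complex noise calibrated to the measured precision) plus a co-located
   fiber-optic-style probe channel, so the entire pipeline is testable
   without scanner data.

## Worked example

Fit the packaged calibration table (ten heating experiments near a copper
wire in agar at 1.5 T, heating-module flip angle 0–90°):

```r
library(wiretherm)

tab <- load_calibration_table()
fit_beta(tab, "fa_deg", "tmax_C", model = "quadratic")
#> <beta_fit> T = 0.004294 * fa_deg^2 | se 0.00013, R^2 0.992
```

The peak temperature grows with the *square* of the heating flip angle at
4.29×10⁻³ °C/deg² — at 90° this setup reached ≈32 °C above baseline.

Calibrate the heating model on synthetic heating curves and predict a new
sequence:

```r
ds <- make_calibration_dataset(
  powers = c(5, 10, 15, 20, 25),
  truth_alpha_poly = c(0.03, 0.002, -2e-5),
  truth_tau_poly   = c(9, -0.15, 0.004),
  noise_sd = 0.2, seed = 1)

fits <- lapply(c(5, 10, 15, 20, 25), function(p)
  fit_eq1(dplyr::filter(ds$curves, power == p), heating_window(10, 90), p))
fits[[3]]
#> <eq1_fit> alpha = 0.05577 +/- 0.00052 degC/W/s, tau = 7.613 +/- 0.11 s | P0 = 15 W, RMSE 0.195 degC

cs <- fit_power_polynomials(fits)
predict_for_sequence(cs, sequence_spec(power = 12.5, duration = 60,
                                       label = "2D TSE-like"))
#> <sequence_prediction> 2D TSE-like: P = 12.5 W for 60 s -> Tmax = 10.91 degC
```

A 12.5 W sequence running for 60 s is predicted to heat the wire tip by
about 10.9 °C — well past the ≈6 °C rise at which tissue damage begins, so
this exposure would be flagged as unacceptable. `autoplot()` works on every
fitted object (`eq1_fit`, `beta_fit`, `calibration_set`,
`sequence_prediction`, `isotherm_grid`), and `tidy()`/`glance()` return the
estimates as tibbles.

End-to-end image processing uses `run_simulate()` → `run_reconstruct()` →
`run_calibrate()` → `run_predict()`, or the thin CLI at
`inst/cli/wiretherm.R` with the same four subcommands.

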