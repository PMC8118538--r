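---
title: "Methods: PRFS thermometry and heating prediction near implanted wires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRFS thermometry and heating prediction near implanted wires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiretherm)
```

## What the package computes

`wiretherm` covers the offline processing of a calibration-based MRI safety
assessment for implanted conductive wires: reconstruct temperature-change
maps from dynamic phase images, quantify the precision and accuracy of that
thermometry, fit a physical heating model to calibration curves acquired at
several RF power levels, and predict the maximal temperature rise that any
other MRI sequence — abstracted to its effective emitted power and duration
— would produce at the same hotspot.

## PRFS reconstruction

The water proton resonance frequency shifts linearly with temperature at
c = −0.0094 ppm/°C. In a gradient-echo acquisition this appears as a phase
change, so a temperature change relative to a reference is

ΔT = Δφ / (2π · γ · B₀ · c · TE),

with γ = 42.576 MHz/T. At TE = 18 ms and B₀ = 1.5 T one degree corresponds
to −0.0679 rad. Reconstruction choices:

* **Reference phase** is the argument of the *complex* mean of the first 10
  dynamics (`n_reference`, configurable). Complex averaging is exact at the
  ±π wrap, where an arithmetic mean of phase values fails; it also reduces
  reference noise by √10.
* **Temporal phase differences** are wrapped to (−π, π] before conversion.
  No spatial unwrapping is attempted: heating is tracked incrementally
  against the reference, as real-time pipelines do. Per-dynamic temperature
  excursions beyond ±π·|k|⁻¹ ≈ ±46 °C at the default settings would alias;
  the intended operating range (tens of degrees sampled every second) stays
  well inside it.
* Images are indexed `[dynamic, slice, row, col]`, 1-based; temperatures are
  increases above baseline, not absolute.

## Drift correction

Scanner field drift produces slow spatio-temporal phase trends that read as
spurious temperature. The published descriptions of this correction specify
a temporal sliding window over the last 10 stacks but not the spatial model,
so the package makes the spatial side explicit and configurable: for each
dynamic and slice an in-plane polynomial of order `spatial_order` (default
0, a scalar offset) is fit over a background mask excluding the heated
region, the fitted fields are smoothed with a trailing 10-dynamic moving
average, and the smoothed background is subtracted everywhere. With the
default order-0 model this removes any uniform drift while leaving a
drift-free series untouched (verified to 10⁻¹⁰ °C in the tests). Higher
orders absorb smooth spatial gradients at the cost of needing a richer
background mask; order 0 is the safe default when the mask is small.
`run_reconstruct()` builds an automatic mask from the lowest quartile of
end-of-heating |ΔT| when none is supplied; a deliberate mask drawn away
from the wire is better when geometry is known.

## Temporal filtering

A first-order Butterworth low-pass at 0.04 Hz (1 Hz sampling) is applied
causally, pixel by pixel, with the filter state initialized to steady state
at the first sample (no start-up transient; DC gain exactly 1). A causal
single pass is used rather than zero-phase forward–backward filtering
because the method this package implements runs during acquisition, where
only past samples exist; the cost is a latency of about three samples,
which downstream comparisons compensate by advancing the filtered curve
(`lag_samples`, default 3 — a fixed convention, not computed from the
filter, whose discrete group delay at DC is ≈3.96 samples; three repetition
times is the operational latency the method is specified with). For white
noise the expected std reduction is the square root of the ratio of the
equivalent noise bandwidth (fc·π/2) to the Nyquist bandwidth, ≈0.354: an
unfiltered per-pixel temporal sd of 0.65 °C becomes ≈0.22 °C over a
120-sample series (slightly below 0.65×0.354 = 0.23 because sample standard
deviations of strongly autocorrelated series are biased low at this length).

## The heating model

Near the wire tip the heat source is well approximated by an isotropic
Gaussian driven at constant power P₀ between t₀ and t₁. The temperature at
the hottest point then follows a piecewise-logarithmic curve,

* 0 for t ≤ t₀,
* α·P₀·τ·ln((t − t₀ + τ)/τ) during heating,
* α·P₀·τ·ln((t − t₀ + τ)/(t − t₁ + τ)) during cooling,

continuous at both switch points, increasing during heating, decreasing
during cooling, and vanishing as t → ∞. α (°C·W⁻¹·s⁻¹) measures how
efficiently emitted power converts to local heating; τ (s) reflects source
size and thermal diffusivity. Units are fixed so that α·P₀·τ is in °C.

`fit_eq1()` estimates (α, τ) by bounded nonlinear least squares
(Levenberg–Marquardt), initialized with τ at 10% of the heating duration and
α solved from the observed end-of-heating level via the closed form, with
restarts from five log-spaced τ values. If no start converges — which is the
expected route for signal-free control curves, where the τ-gradient vanishes
— the model's conditional linearity in α is exploited: a 60-point
logarithmic τ grid with the α ≥ 0 closed-form solution at each node gives
the least-squares pair directly. Fits whose α lies within two standard
errors of zero are flagged `low_signal`.

### Calibration across powers and prediction

Physically α and τ should not depend on the applied power, but at low power
the heated spot is small relative to the voxel and partial-volume effects
bias both parameters, so they drift with P in practice. The package follows
the semi-empirical route: fit (αᵢ, τᵢ) per calibration power Pᵢ, then
second-order polynomials α(P) and τ(P) by ordinary least squares
(`fit_power_polynomials()`, ≥3 distinct powers). Prediction for a sequence
of effective power P and duration D evaluates the polynomials at P and the
model over the window (0, D). Two guardrails:

* if α(P) < 0 or τ(P) ≤ 0 the prediction is *refused* with a domain error
  rather than clipped — extrapolated quadratics behave badly outside the
  fitted range, and a silently clipped value would be mistaken for a
  physical estimate (in `isotherm_grid()` such cells become `NA`);
* powers outside the calibrated range are allowed but flagged
  `extrapolated`.

Zero-power queries return a zero curve without consulting the polynomials:
no emitted power, no RF heating, regardless of how the polynomials
extrapolate to P = 0.

### Calibration-table fits

Peak temperature against flip angle and against B₁⁺rms are fit as
origin-constrained quadratics T = β·x², and against emitted energy as an
origin-constrained line T = β·E (`fit_beta()`; an intercept variant exists
but is not the default). The origin constraint encodes the physics — no
excitation, no heating — and, on the packaged table, reproduces the
coefficients that an unconstrained fit smears: β₁ = 4.29×10⁻³ °C/deg² and
β₂ = 2.00 °C/μT². The energy coefficient β₃ is computed and reported but is
documented (`energy_estimate()`) as the naive estimator: applied to other
sequences it mispredicts the peak badly, because the peak near a wire
depends on power, not energy alone — that failure is the motivation for the
full model above.

## Sequence bookkeeping

* **Duty cycle**: a train of n pulses of duration p separated by gaps g
  occupies n·p + (n−1)·g of each TR — n pulse durations but only n−1 gaps.
  For the default 242 × (1 ms, 2 ms) train in a 1 s TR this is 724 ms, a 72%
  duty cycle; counting n gaps would give 72.6% and round to 73%, which does
  not match the instrument read-out this model reproduces.
* **Energy scaling**: with a fixed pulse shape, energy scales with FA². The
  table output truncates to whole joules rather than rounding half-up:
  truncation reproduces the reference table's 80° entry (9627 J) exactly and
  every other row within 1 J, so it is taken as the console's convention.
* **B₁⁺rms combination**: the imaging baseline and the FA-proportional
  heating contribution add in quadrature (root-sum-square of independent RF
  power contributions). This is a model of the scanner's reported value, not
  an exact reproduction — measured read-outs carry ≈0.1 μT rounding noise,
  and the packaged table's 80° entry deviates by 0.14 μT.
* `n_pulses` is always an input: the pulse count a scanner fits into the
  TR budget is not derivable from the stated timing alone.

## Synthetic acquisitions

`simulate_temperature_field()` builds ΔT(pixel, t) as the heating model at
the hotspot center times an isotropic spatial Gaussian (default σ = 1.7 mm,
FWHM 4.0 mm — mid-range for the few-millimetre hotspots seen at wire tips;
observed widths span roughly 2.4–5.6 mm). `simulate_complex_series()`
inverts the PRFS relation into phase, adds a smooth low-order 2-D polynomial
baseline (amplitude ≤ π/2, exercising wrap-free reference subtraction), an
optional uniform phase drift per dynamic, and complex Gaussian noise. The
default per-component noise sd (4.41% of magnitude) is set so the
*unfiltered* temporal temperature sd is ≈0.65 °C at TE 18 ms / 1.5 T, the
precision the thermometry it emulates achieves; at this SNR phase noise is
Gaussian to excellent approximation. A co-located probe channel
(`simulate_probe()`) samples the truth with independent sensor noise and no
filter lag. All generators are pure functions of their seed.

What the generator does *not* emulate: EPI ghosting, susceptibility
distortion and signal dropout near the wire, motion, perfusion, and
spatially varying coil sensitivity. Passing tests therefore demonstrate the
correctness of the *processing* — reconstruction algebra, filter behaviour,
model fitting, prediction plumbing — under the stated statistical model,
not robustness to those acquisition artifacts.

## Numerical conventions and degenerate inputs

* Quantiles use linear interpolation between order statistics (type 7).
* `hottest_pixel()` breaks ties deterministically: the first maximal pixel
  in `[slice, row, col]` (column-major) order. Its end-of-heating summary is
  the mean over a 5-dynamic window (default dynamics 86–90).
* FWHM is measured on the 1-D profile through the hotspot by linear
  interpolation at half maximum; a profile that never falls below half
  maximum on one side extends to the image edge, and flat or non-positive
  profiles raise a no-peak error.
* Empty masks/ROIs, non-positive TE/B₀/τ, lags exceeding the series, fewer
  than 3 calibration powers, and missing metadata fields all raise classed
  errors (`wiretherm_input_error`, `wiretherm_config_error`,
  `wiretherm_fit_error`, `wiretherm_domain_error`) rather than returning
  partial results.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
10⁴ simulated pixels for the filter-precision study, 100 replicates of the
validation heating experiment (truth peaking at 11.5 °C, 0.65 °C noise),
500 replicates of the (α, τ) recovery study at 0.2 °C noise, and small
(≤2 slice, ≤32² pixel, 120-dynamic) image series for the end-to-end loops.
These sizes give Monte-Carlo error comfortably below the tolerances being
checked while keeping the default run fast.

## Known limitations

* PRFS thermometry is invalid in fat; the package assumes aqueous tissue or
  gel throughout.
* Drift correction with an automatic mask can absorb a small fraction of
  very broad hotspots; supply an explicit background mask when the heated
  region is large relative to the field of view.
* The quadratic α(P), τ(P) parameterization is an interpolation device, not
  physics: predictions outside the calibrated power range are flagged, and
  refusal at nonphysical polynomial values is deliberate.
* Probe-versus-MR comparisons assume the probe sits at the hottest pixel; a
  1-pixel offset biases the comparison by the local spatial gradient.
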