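Package: wiretherm
Title: PRFS MR Thermometry and RF-Heating Prediction Near Implanted Wires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs temperature-change maps from dynamic complex
    (phase) MR image series using the proton resonance frequency shift
    (PRFS) method, with background phase-drift correction and causal
    temporal low-pass filtering as used in real-time thermometry
    pipelines. Fits the piecewise-logarithmic temperature response of a
    Gaussian heat source at constant power to calibration heating curves
    acquired near implanted conductive wires, parameterizes the absorption
    coefficient and time constant as polynomials in applied power, and
    predicts the maximal RF-induced temperature rise of arbitrary MRI
    sequences from their emitted power and duration, including isotherm
    safety charts. Ships a synthetic acquisition generator (Gaussian
    hotspot, background drift, complex noise, co-located probe channel) so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
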