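test_that("reference phase is the argument of the complex mean", {
  # identical phase images pass through unchanged
  phi0 <- array(runif(2 * 8 * 8, -1, 1), c(2, 8, 8))
  data <- array(complex(argument = rep(phi0, each = 12)), c(12, 2, 8, 8))
  for (t in 1:12) data[t, , , ] <- complex(modulus = 1, argument = phi0)
  s <- complex_series(data, 0:11, 0.8, te = 0.018, b0 = 1.5, tr = 1)
  expect_equal(build_reference(s, 10), phi0, tolerance = 1e-12)

  # at the +/- pi wrap the complex mean stays at pi, not zero
  d2 <- array(complex(real = 0), c(2, 1, 1, 1))
  d2[1, 1, 1, 1] <- complex(argument = pi - 0.01)
  d2[2, 1, 1, 1] <- complex(argument = -pi + 0.01)
  s2 <- complex_series(d2, 0:1, 0.8, te = 0.018, b0 = 1.5, tr = 1)
  expect_equal(abs(build_reference(s2, 2)[1, 1, 1]), pi, tolerance = 1e-9)

  expect_error(build_reference(s2, 5), class = "wiretherm_input_error")
})

test_that("averaging n reference dynamics reduces phase noise by sqrt(n)", {
  set.seed(11)
  sigma_phi <- 0.05
  npix <- 1e5
  phi <- matrix(rnorm(10 * npix, 0, sigma_phi), nrow = 10)
  data <- array(complex(modulus = 1, argument = phi), c(10, 1, 250, 400))
  s <- complex_series(data, 0:9, 0.8, te = 0.018, b0 = 1.5, tr = 1)
  ref <- build_reference(s, 10)
  expect_equal(sd(ref), sigma_phi / sqrt(10), tolerance = 0.03)
})

test_that("PRFS conversion matches the closed form and is linear", {
  # -0.067895 rad at TE 18 ms, 1.5 T is one degree
  expect_equal(phase_to_temperature(-0.067895, 0.018, 1.5), 1.0,
               tolerance = 1e-4)
  expect_identical(phase_to_temperature(0, 0.018, 1.5), 0)
  dphi <- runif(20, -3, 3)
  for (a in c(-2, 0.5, 3)) {
    expect_equal(phase_to_temperature(a * dphi, 0.018, 1.5),
                 a * phase_to_temperature(dphi, 0.018, 1.5), tolerance = 1e-12)
  }
  expect_error(phase_to_temperature(1, te = -1, b0 = 1.5),
               class = "wiretherm_config_error")
  expect_error(phase_to_temperature(1, te = 0.018, b0 = 0),
               class = "wiretherm_config_error")
})

test_that("drift correction is inert on drift-free data and removes linear drift", {
  s <- block_series()
  cfg <- drift_config(background_mask = block_mask())
  corrected <- correct_drift(s, cfg)
  expect_lt(max(abs(corrected$dT - s$dT)), 1e-10)
  expect_true(corrected$drift_corrected)

  # uniform 0.01 degC/dynamic drift on every pixel
  drifted <- s
  for (t in seq_along(s$times)) drifted$dT[t, , , ] <- s$dT[t, , , ] + 0.01 * (t - 1)
  fixed <- correct_drift(drifted, cfg)
  bg_means <- sapply(seq_along(s$times),
                     function(t) mean(fixed$dT[t, , , ][cfg$background_mask]))
  expect_lt(max(abs(bg_means)), 0.05)
  # hotspot trajectory distorted by less than the drift amplitude
  hot_err <- max(abs(fixed$dT[, 1, 8, 8] - s$dT[, 1, 8, 8]))
  expect_lt(hot_err, 0.01 * (length(s$times) - 1))

  expect_error(correct_drift(s, drift_config(background_mask = array(FALSE, c(1, 16, 16)))),
               class = "wiretherm_input_error")
  expect_error(correct_drift(s, drift_config()), class = "wiretherm_input_error")
})

test_that("causal low-pass has unit DC gain, known noise reduction and lag metadata", {
  const <- rep(2.5, 60)
  expect_equal(lowpass_filter_curve(const), const, tolerance = 1e-12)

  # white-noise std reduction close to the equivalent-noise-bandwidth value
  set.seed(21)
  x <- matrix(rnorm(120 * 500), 120)
  y <- apply(x, 2, lowpass_filter_curve)
  factor <- mean(apply(y[11:120, ], 2, sd)) / mean(apply(x[11:120, ], 2, sd))
  expect_gt(factor, 0.30)
  expect_lt(factor, 0.40)

  s <- block_series()
  f <- lowpass_filter(s)
  expect_true(f$filtered)
  expect_identical(f$lag_samples, 3L)
  # filtering an image series equals filtering each pixel curve
  expect_equal(f$dT[, 1, 8, 8], lowpass_filter_curve(s$dT[, 1, 8, 8]),
               tolerance = 1e-12)

  expect_error(filter_config(cutoff_hz = 0.6, sampling_hz = 1),
               class = "wiretherm_config_error")
  short <- temperature_series(array(0, c(5, 1, 2, 2)), 0:4, 0.8)
  expect_error(lowpass_filter(short), class = "wiretherm_input_error")
})

test_that("precision maps equal a brute-force two-pass standard deviation", {
  set.seed(31)
  s <- block_series()
  s$dT <- s$dT + array(rnorm(length(s$dT), 0, 0.65), dim(s$dT))
  pm <- precision_maps(s)
  expect_true(all(pm$sigma >= 0))
  d <- dim(s$dT)
  for (idx in list(c(1, 1, 1), c(1, 8, 8), c(1, 16, 3))) {
    v <- s$dT[, idx[1], idx[2], idx[3]]
    mu2 <- sum(v) / length(v)
    expect_equal(pm$mu[idx[1], idx[2], idx[3]], mu2, tolerance = 1e-12)
    expect_equal(pm$sigma[idx[1], idx[2], idx[3]],
                 sqrt(sum((v - mu2)^2) / (length(v) - 1)), tolerance = 1e-12)
  }
  const <- temperature_series(array(1.5, c(20, 1, 4, 4)), 0:19, 0.8)
  expect_true(all(precision_maps(const)$sigma == 0))
  one <- temperature_series(array(0, c(1, 1, 4, 4)), 0, 0.8)
  expect_error(precision_maps(one), class = "wiretherm_input_error")
})

test_that("ROI box statistics use the linear-interpolation quantile convention", {
  m <- array(1:100, c(1, 10, 10))
  roi <- array(TRUE, c(1, 10, 10))
  st <- roi_box_stats(m, roi)
  expect_equal(st$q1, 25.75)
  expect_equal(st$median, 50.5)
  expect_equal(st$q3, 75.25)
  expect_equal(st$lower, 1)

  cm <- array(2, c(1, 5, 5))
  stc <- roi_box_stats(cm, array(TRUE, c(1, 5, 5)))
  expect_true(all(unlist(stc) == 2))

  set.seed(41)
  half_gauss <- array(abs(rnorm(400, 0, 0.2)), c(1, 20, 20))
  sth <- roi_box_stats(half_gauss, array(TRUE, c(1, 20, 20)))
  v <- as.vector(half_gauss)
  expect_equal(unlist(sth, use.names = FALSE),
               sapply(c(0, 0.25, 0.5, 0.75, 0.95), quantile_oracle, x = v),
               tolerance = 1e-12)

  expect_error(roi_box_stats(m, array(FALSE, c(1, 10, 10))),
               class = "wiretherm_input_error")
})

test_that("lag-compensated RMSE behaves as an alignment metric", {
  x <- sin(seq(0, 4, length.out = 50))
  expect_equal(rmse_with_lag(x, x, 0), 0)
  delayed <- c(rep(x[1], 3), x[1:47])  # x delayed by 3 samples
  expect_equal(rmse_with_lag(delayed, x, 3), 0)
  expect_error(rmse_with_lag(x, x, 50), class = "wiretherm_input_error")
  expect_error(rmse_with_lag(x, x, -1), class = "wiretherm_input_error")
})

test_that("hottest pixel is found from the end-of-heating mean", {
  truth <- tiny_truth()
  s <- temperature_series(truth$dT, truth$times, 0.8)
  hp <- hottest_pixel(s, c(87, 91))  # dynamics at t = 86..90 s
  expect_identical(hp$pixel, truth$center)
  p <- eq1_params(0.05, 8, 20)
  expected <- mean(eq1_eval(p, default_window(), 86:90))
  expect_equal(hp$tmax, expected, tolerance = 1e-12)
  expect_equal(hp$tmax_sd, sd(eq1_eval(p, default_window(), 86:90)),
               tolerance = 1e-12)

  zero <- temperature_series(array(0, c(20, 1, 4, 4)), 0:19, 0.8)
  hz <- hottest_pixel(zero, c(16, 20))
  expect_equal(hz$tmax, 0)
  expect_identical(hz$pixel, c(1L, 1L, 1L))  # deterministic tie-break

  expect_error(hottest_pixel(s, c(100, 130)), class = "wiretherm_input_error")
})

test_that("FWHM of a Gaussian profile is 2.3548 sigma", {
  sp <- 0.8
  sigma_mm <- 1.7
  x <- ((1:41) - 21) * sp
  prof <- exp(-x^2 / (2 * sigma_mm^2))
  map <- outer(prof, prof)
  expect_equal(fwhm_profile(map, c(21, 21), sp), 2.3548 * sigma_mm,
               tolerance = 0.02)
  expect_equal(fwhm_profile(map, c(21, 21), sp, axis = "row"),
               2.3548 * sigma_mm, tolerance = 0.02)

  # delta-like single hot pixel: width bounded by the pixel spacing
  dmap <- matrix(0, 9, 9); dmap[5, 5] <- 1
  expect_lte(fwhm_profile(dmap, c(5, 5), 0.8), 1.6)

  expect_error(fwhm_profile(matrix(1, 5, 5), c(3, 3), 0.8),
               class = "wiretherm_nopeak_error")
  expect_error(fwhm_profile(matrix(-1, 5, 5), c(3, 3), 0.8),
               class = "wiretherm_nopeak_error")
})
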