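test_that("heat-source model matches its closed form on both branches", {
  p <- eq1_params(0.1, 5, 10)
  w <- heating_window(0, 80)
  expect_equal(eq1_eval(p, w, 0), 0)
  expect_equal(eq1_eval(p, w, -5), 0)
  expect_equal(eq1_eval(p, w, 80), 5 * log(17), tolerance = 1e-12)
  expect_equal(eq1_eval(p, w, 85), 5 * log(90 / 10), tolerance = 1e-12)
  expect_equal(eq1_eval(p, w, 1e9), 0, tolerance = 1e-5)
  expect_equal(eq1_peak(p, w), eq1_eval(p, w, 80))
  expect_error(eq1_params(0.1, -1, 10), class = "wiretherm_input_error")
})

test_that("model is continuous and monotone for random positive parameters", {
  set.seed(7)
  for (i in 1:25) {
    p <- eq1_params(runif(1, 0.01, 1), runif(1, 0.5, 30), runif(1, 1, 50))
    t0 <- runif(1, 0, 20); t1 <- t0 + runif(1, 5, 100)
    w <- heating_window(t0, t1)
    # branch formulas agree at the switch points
    a <- p$alpha * p$p0 * p$tau
    expect_lt(abs(eq1_eval(p, w, t0)), 1e-12)
    expect_lt(abs(eq1_eval(p, w, t1) - a * log((t1 - t0 + p$tau) / p$tau)), 1e-12)
    eps <- 1e-9
    expect_lt(abs(eq1_eval(p, w, t0 + eps) - eq1_eval(p, w, t0 - eps)), 1e-6)
    expect_lt(abs(eq1_eval(p, w, t1 + eps) - eq1_eval(p, w, t1 - eps)), 1e-6)
    # strictly increasing during heating, strictly decreasing after
    th <- seq(t0 + 0.01, t1, length.out = 40)
    expect_true(all(diff(eq1_eval(p, w, th)) > 0))
    tc <- seq(t1 + 0.01, t1 + 200, length.out = 40)
    expect_true(all(diff(eq1_eval(p, w, tc)) < 0))
    # peak increases with heating duration
    expect_gt(eq1_peak(p, heating_window(t0, t1 + 10)), eq1_peak(p, w))
  }
  expect_equal(eq1_peak(eq1_params(0, 5, 10), heating_window(0, 80)), 0)
})

test_that("fitting recovers parameters exactly from noiseless curves", {
  w <- heating_window(10, 90)
  curve <- tibble::tibble(
    time_s = 0:119,
    temp_C = eq1_eval(eq1_params(0.05, 8, 20), w, 0:119))
  f <- fit_eq1(curve, w, p0 = 20)
  expect_equal(f$params$alpha, 0.05, tolerance = 1e-7)
  expect_equal(f$params$tau, 8, tolerance = 1e-7)
  expect_lt(f$rmse, 1e-8)
  expect_false(f$low_signal)
  td <- tidy(f)
  expect_identical(td$term, c("alpha", "tau"))
  expect_equal(td$estimate, c(0.05, 8), tolerance = 1e-7)
  expect_equal(glance(f)$peak, eq1_peak(eq1_params(0.05, 8, 20), w),
               tolerance = 1e-7)
})

test_that("fitting stays within 5% of truth under measurement noise", {
  w <- heating_window(10, 90)
  clean <- eq1_eval(eq1_params(0.05, 8, 20), w, 0:119)
  ok <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    set.seed(s)
    f <- fit_eq1(tibble::tibble(time_s = 0:119,
                                temp_C = clean + rnorm(120, 0, 0.2)),
                 w, p0 = 20)
    if (abs(f$params$alpha - 0.05) / 0.05 < 0.05 &&
        abs(f$params$tau - 8) / 8 < 0.05) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("a pure-noise curve is flagged as low signal with alpha near zero", {
  set.seed(99)
  w <- heating_window(10, 90)
  f <- fit_eq1(tibble::tibble(time_s = 0:119, temp_C = rnorm(120, 0, 0.2)),
               w, p0 = 20)
  expect_true(f$low_signal)
  expect_lt(f$params$alpha * 20 * f$params$tau *
              log((80 + f$params$tau) / f$params$tau), 0.3)
  expect_error(fit_eq1(tibble::tibble(time_s = 0:50, temp_C = rnorm(51)),
                       w, p0 = 20), class = "wiretherm_input_error")
  expect_error(fit_eq1(tibble::tibble(time_s = 0:119, temp_C = rnorm(120)),
                       w, p0 = 0), class = "wiretherm_input_error")
})

test_that("power polynomials interpolate three points and match the normal equations", {
  fits3 <- tibble::tibble(power = c(5, 10, 20),
                          alpha = c(0.04, 0.05, 0.045),
                          tau = c(6, 8, 9))
  cs <- fit_power_polynomials(fits3)
  for (i in 1:3) {
    expect_equal(wiretherm:::polyval_asc(cs$alpha_poly, fits3$power[i]),
                 fits3$alpha[i], tolerance = 1e-9)
    expect_equal(wiretherm:::polyval_asc(cs$tau_poly, fits3$power[i]),
                 fits3$tau[i], tolerance = 1e-9)
  }
  expect_identical(cs$power_range, c(5, 20))

  # duplicated powers: least squares equals the normal-equation oracle
  fits_dup <- tibble::tibble(power = c(5, 5, 10, 20),
                             alpha = c(0.04, 0.05, 0.05, 0.045),
                             tau = c(6, 7, 8, 9))
  cd <- fit_power_polynomials(fits_dup)
  X <- cbind(1, fits_dup$power, fits_dup$power^2)
  expect_equal(cd$alpha_poly,
               as.numeric(solve(crossprod(X), crossprod(X, fits_dup$alpha))),
               tolerance = 1e-9)
  expect_equal(cd$tau_poly,
               as.numeric(solve(crossprod(X), crossprod(X, fits_dup$tau))),
               tolerance = 1e-9)

  expect_error(fit_power_polynomials(fits3[1:2, ]),
               class = "wiretherm_input_error")
})

test_that("sequence prediction closes the loop on a known truth model", {
  a_poly <- c(0.03, 0.002, -2e-5)
  t_poly <- c(9, -0.15, 0.004)
  powers <- c(5, 10, 15, 20, 25)
  fits <- tibble::tibble(power = powers,
                         alpha = sapply(powers, function(p) wiretherm:::polyval_asc(a_poly, p)),
                         tau = sapply(powers, function(p) wiretherm:::polyval_asc(t_poly, p)))
  cs <- fit_power_polynomials(fits)

  # held-out interior power
  p_q <- 12.5
  truth_peak <- eq1_peak(
    eq1_params(wiretherm:::polyval_asc(a_poly, p_q),
               wiretherm:::polyval_asc(t_poly, p_q), p_q),
    heating_window(0, 60))
  pred <- predict_for_sequence(cs, sequence_spec(p_q, 60))
  expect_equal(pred$tmax, truth_peak, tolerance = 0.02)
  expect_false(pred$extrapolated)
  expect_equal(max(pred$curve$temp_C), pred$tmax, tolerance = 1e-9)

  expect_equal(predict_for_sequence(cs, sequence_spec(0, 60))$tmax, 0)
  expect_true(predict_for_sequence(cs, sequence_spec(30, 60))$extrapolated)

  # peak nondecreasing in duration at fixed power
  tm <- sapply(c(10, 30, 60, 120),
               function(d) predict_for_sequence(cs, sequence_spec(p_q, d))$tmax)
  expect_true(all(diff(tm) >= 0))
})

test_that("prediction refuses a power where the polynomials turn nonphysical", {
  fits <- tibble::tibble(power = c(1, 2, 3),
                         alpha = c(0.05, 0.03, 0.01),  # alpha(P) = 0.07 - 0.02 P
                         tau = c(5, 5, 5))
  cs <- fit_power_polynomials(fits)
  expect_error(predict_for_sequence(cs, sequence_spec(5, 30)),
               class = "wiretherm_domain_error")
  g <- isotherm_grid(cs, powers = c(1, 2, 5), durations = c(10, 20))
  expect_true(all(is.na(g$tmax[g$power == 5])))
})

test_that("isotherm grid cells equal scalar predictions and grow with duration", {
  fits <- tibble::tibble(power = c(5, 10, 20),
                         alpha = c(0.04, 0.05, 0.045),
                         tau = c(6, 8, 9))
  cs <- fit_power_polynomials(fits)
  powers <- c(5, 10, 15)
  durations <- c(10, 30, 60, 90)
  g <- isotherm_grid(cs, powers, durations)
  for (i in seq_len(nrow(g))) {
    expect_equal(g$tmax[i],
                 predict_for_sequence(cs, sequence_spec(g$power[i], g$duration[i]))$tmax,
                 tolerance = 1e-12)
  }
  for (p in powers) {
    expect_true(all(diff(g$tmax[g$power == p][order(g$duration[g$power == p])]) >= 0))
  }
})

test_that("calibration-curve fits equal the normal-equation oracle", {
  tab <- load_calibration_table()
  b1 <- fit_beta(tab, "fa_deg", "tmax_C", model = "quadratic")
  expect_equal(b1$beta, sum(tab$fa_deg^2 * tab$tmax_C) / sum(tab$fa_deg^4),
               tolerance = 1e-12)
  b3 <- fit_beta(tab, "energy_J", "tmax_C", model = "linear")
  expect_equal(b3$beta, sum(tab$energy_J * tab$tmax_C) / sum(tab$energy_J^2),
               tolerance = 1e-12)

  # exact quadratic data
  x <- 1:8
  # exact data: lm warns that the fit is perfect, which is the point here
  ex <- suppressWarnings(fit_beta(tibble::tibble(x = x, y = 3 * x^2), "x", "y"))
  expect_equal(ex$beta, 3, tolerance = 1e-12)
  expect_equal(ex$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_beta(tibble::tibble(x = c(0, 0), y = c(1, 2)), "x", "y"),
               class = "wiretherm_input_error")
  expect_error(fit_beta(tibble::tibble(x = 1, y = 1), "x", "y"),
               class = "wiretherm_input_error")

  # intercept variant reduces to lm
  bi <- fit_beta(tab, "fa_deg", "tmax_C", intercept = TRUE)
  lm_ref <- lm(tmax_C ~ I(fa_deg^2), data = tab)
  expect_equal(bi$beta, unname(coef(lm_ref)[2]), tolerance = 1e-12)
})

test_that("the naive energy estimator is a plain linear scaling", {
  expect_equal(energy_estimate(2.3e-3, 12185), 28.0255, tolerance = 1e-6)
  expect_equal(energy_estimate(2.3e-3, 0), 0)
  expect_equal(energy_estimate(2.3e-3, 2 * 500),
               2 * energy_estimate(2.3e-3, 500))
})
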