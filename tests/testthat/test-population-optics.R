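test_that("width law and log-base conversion", {
  expect_equal(sigma_from_mean(1), 0.168)
  expect_equal(sigma_from_mean(0), 0.115)  # formal intercept
  expect_equal(sigma_from_mean(4), 0.327)
  expect_equal(sigma_to_ln(0.168), log(10) * 0.168)
  expect_error(sigma_from_mean(-1), "non-negative")
})

test_that("length sampling: reproducibility, degenerate case, moments", {
  expect_identical(sample_lengths(3, 0, 5), rep(3, 5))
  expect_identical(sample_lengths(3, 0.3, 100, seed = 9),
                   sample_lengths(3, 0.3, 100, seed = 9))
  # law of large numbers: geometric mean and log-SD recovered
  x <- sample_lengths(3, 0.274, 1e5, seed = 1)
  expect_equal(exp(mean(log(x))), 3, tolerance = 0.01)
  expect_equal(stats::sd(log(x)), 0.274, tolerance = 0.02)
  # caller's RNG stream is untouched by seeded draws
  set.seed(123); a <- stats::runif(1)
  set.seed(123); invisible(sample_lengths(2, 0.2, 10, seed = 77)); b <- stats::runif(1)
  expect_identical(a, b)
  expect_error(sample_lengths(3, 0.3, 0), ">= 1")
  expect_error(sample_lengths(-1, 0.3, 10), "positive")
})

test_that("ensemble intensity: monodisperse reduction, quadrature vs MC, limits", {
  # sigma = 0 reduces the ensemble ratio to the single-length ratio
  for (lf in c(1, 3, 6)) {
    expect_equal(ensemble_ratio(lf, 0), single_length_ratio(ulf_to_length(lf)),
                 tolerance = 1e-10)
  }
  # quadrature and Monte Carlo agree to < 1%
  cases <- list(c(1, 0.168), c(3, 0.274), c(8, 0.539))
  for (cs in cases) {
    sig <- sigma_to_ln(cs[2])
    for (wl in c(405, 594)) {
      q <- ensemble_intensity(cs[1], sig, wl)
      m <- ensemble_intensity(cs[1], sig, wl, method = "mc", n_mc = 1e5,
                              seed = 1000 + wl + round(10 * cs[1]))
      expect_lt(abs(m - q) / q, 0.01)
    }
  }
  # Rayleigh limit: vanishing mean length gives ratio ~ 1
  expect_equal(ensemble_ratio(0.01, 0.1), 1, tolerance = 0.01)
  expect_error(ensemble_intensity(3, 2.5, 405), "sigma")
})

test_that("ensemble ratio never exceeds the wavelength ratio", {
  set.seed(4)
  for (i in 1:20) {
    lf <- stats::runif(1, 0.5, 30)
    sig <- sigma_to_ln(stats::runif(1, 0, 0.6))
    expect_lte(ensemble_ratio(lf, sig), 594 / 405 + 1e-9)
  }
})

test_that("ratio curve: flat at rate zero, start value, exponential shape", {
  g0 <- growth_model(0)
  rc0 <- ratio_curve(g0, c(0, 1, 5, 10))
  expect_equal(diff(range(rc0$ratio)), 0, tolerance = 1e-12)
  # start value equals the blurred single-ULF ensemble ratio
  g1 <- growth_model(1)
  expect_equal(ratio_curve(g1, 0)$ratio,
               ensemble_ratio(1, sigma_to_ln(sigma_from_mean(1))),
               tolerance = 1e-10)
  # well-approximated by 1 + A(1 - exp(-t/tau))
  tm <- exp(seq(log(1), log(600), length.out = 60)) / 60
  for (rate in c(1, 3)) {
    rc <- ratio_curve(growth_model(rate), tm)
    f <- fit_ratio_model(data.frame(time_s = rc$time_min * 60, ratio = rc$ratio),
                         factor_used = NA)
    expect_lt(f$rms, 0.03)
  }
})

test_that("doubling the growth rate exactly halves the time axis", {
  tm <- c(0.25, 0.5, 1, 2, 4)
  slow <- ratio_curve(growth_model(1.3), 2 * tm)
  fast <- ratio_curve(growth_model(2.6), tm)
  expect_equal(fast$ratio, slow$ratio, tolerance = 1e-12)
})

test_that("rate-factor calibration: diagnostics, conventions, sensitivity", {
  cal <- calib_cached(normalize_start = FALSE)
  expect_s3_class(cal, "sf_calibration")
  expect_true(all(cal$fits$converged))
  expect_gt(cal$r_squared, 0.99)
  # self-consistency within the raw convention: factor/tau recovers each
  # generating rate within 10%
  rec <- cal$factor / cal$fits$tau_min
  expect_true(all(abs(rec / cal$fits$rate - 1) < 0.10))
  # the trace-consistent convention gives a distinctly larger factor
  cal_n <- calib_cached(normalize_start = TRUE)
  expect_gt(cal_n$factor, cal$factor + 0.2)
  # monodisperse populations calibrate to a different factor, recording
  # the effect of polydispersity
  cal_mono <- calibrate_rate_factor(rates = c(0.5, 1, 2, 3, 4, 5),
                                    method = "quadrature",
                                    sigma_slope = 0, sigma_intercept = 0)
  expect_gt(abs(cal_mono$factor - cal$factor), 0.05)
  # doubling the width-law intercept: regression stays linear
  cal_wide <- calibrate_rate_factor(method = "quadrature",
                                    sigma_intercept = 0.23)
  expect_gt(cal_wide$r_squared, 0.99)
  expect_gt(abs(cal_wide$factor - cal$factor), 1e-3)
  expect_error(calibrate_rate_factor(rates = c(1, 2)), "3 distinct")
})
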