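test_that("size parameter matches direct arithmetic and its scaling laws", {
  expect_equal(size_parameter(60, 405), 2 * pi * 60 / 405 * sqrt(2) / 2)
  expect_equal(size_parameter(60, 405), 0.6582049, tolerance = 1e-6)
  # strictly increasing in length, decreasing in wavelength
  l <- seq(10, 1000, by = 10)
  expect_true(all(diff(size_parameter(l, 405)) > 0))
  expect_true(all(size_parameter(300, c(405, 500, 594)) ==
                    sort(size_parameter(300, c(405, 500, 594)), decreasing = TRUE)))
  # wavelength cancellation at fixed length
  expect_equal(size_parameter(123, 405) / size_parameter(123, 594), 594 / 405)
  expect_error(size_parameter(0, 405), "positive")
  expect_error(size_parameter(60, -1), "positive")
})

test_that("form factor matches an independent quadrature oracle", {
  # oracle: adaptive quadrature of the sine integral, no Si() involved
  e2_oracle <- function(z)
    stats::integrate(function(w) sin(w) / w, 0, 2 * z, rel.tol = 1e-12)$value / z -
      (sin(z) / z)^2
  expect_identical(length_form_factor(0), 1)
  expect_equal(length_form_factor(1), e2_oracle(1), tolerance = 1e-9)
  expect_equal(length_form_factor(1), 0.8973396, tolerance = 1e-6)
  # value at the 1-ULF, 405 nm working point (spec'd z = 0.6582)
  z1 <- size_parameter(60, 405)
  expect_equal(length_form_factor(z1), e2_oracle(z1), tolerance = 1e-9)
  expect_equal(length_form_factor(z1), 0.953495, tolerance = 1e-6)
  # large-z asymptote pi/(2z) within 2%
  expect_equal(length_form_factor(100), pi / 200, tolerance = 0.02)
  expect_error(length_form_factor(-0.1), "non-negative")
})

test_that("sine-integral evaluation agrees with brute-force trapezoid to 1e-6", {
  for (z in c(0.01, 0.1, 0.66, 1, 5, 17, 50)) {
    w <- seq(1e-9, 2 * z, length.out = 400001)
    f <- sin(w) / w
    si_trap <- sum((f[-1] + f[-length(f)]) / 2) * (w[2] - w[1])
    e2_trap <- si_trap / z - (sin(z) / z)^2
    expect_equal(length_form_factor(z), e2_trap, tolerance = 1e-6)
  }
})

test_that("form factor is continuous, bounded and monotone where it should be", {
  z <- c(seq(1e-6, 9.9e-4, length.out = 50), seq(1e-3, 60, length.out = 2000))
  e2 <- length_form_factor(z)
  expect_true(all(e2 > 0 & e2 <= 1))
  # continuity across the series/special-function switch at z = 1e-3
  expect_equal(length_form_factor(1e-3 - 1e-9), length_form_factor(1e-3 + 1e-9),
               tolerance = 1e-8)
  # decreasing on the working range (up to the first shoulder)
  zz <- seq(0.01, 4, length.out = 500)
  expect_true(all(diff(length_form_factor(zz)) < 0))
})

test_that("fast interpolated form factor matches the reference evaluation", {
  z <- 10^seq(-5, 3.2, length.out = 3000)
  ref <- length_form_factor(z)
  expect_equal(vimscatter:::.e2_fast(z), ref, tolerance = 1e-6)
})

test_that("shape factor has the point-scatterer limit and thin-rod warning", {
  expect_equal(shape_factor(1e-4, 405), 1, tolerance = 1e-8)
  expect_warning(shape_factor(300, 405, radius_nm = 45), "Rayleigh-Gans")
  expect_silent(shape_factor(300, 405, radius_nm = 5))
  # shorter wavelength sees the shape more strongly: P405 <= P594
  l <- seq(5, 500, by = 5)
  expect_true(all(shape_factor(l, 405) <= shape_factor(l, 594)))
})

test_that("single-length ratio: limits, monotone rise, first local maximum", {
  expect_equal(single_length_ratio(1e-3), 1, tolerance = 1e-6)
  # asymptote lambda_long/lambda_short to < 0.5%
  expect_equal(single_length_ratio(1e6), 594 / 405, tolerance = 0.005)
  # >= 1 everywhere and monotone over 1..7 ULF lengths
  n <- seq(1, 7, by = 0.01)
  r <- single_length_ratio(ulf_to_length(n))
  expect_true(all(r >= 1))
  expect_true(all(diff(r) > 0))
  # first local maximum at the ~7-ULF length (paper precision: +/- 1 ULF)
  pk <- ratio_peak_ulf()
  expect_lt(abs(pk$n_peak - 7), 1)
  expect_gt(pk$ratio, 1.4)
})

test_that("ULF count to length mapping and its inverse", {
  expect_equal(ulf_to_length(1), 60)
  expect_equal(ulf_to_length(2), 103)
  expect_equal(ulf_to_length(11), 490)  # the ~500 nm filament
  expect_equal(length_to_ulf(ulf_to_length(c(1, 2.5, 7, 11))), c(1, 2.5, 7, 11))
  expect_equal(length_to_ulf(17 + 43), 1)  # sub-ULF lengths allowed downward
  expect_error(ulf_to_length(0.9), ">= 1")
  expect_error(length_to_ulf(-5), "positive")
  expect_error(ulf_geometry(ulf_length = 0), "positive")
  expect_error(ulf_geometry(ulf_increment = 70), "exceed")
})
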