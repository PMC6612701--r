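test_that("net optical density follows the log pixel-value ratio", {
  expect_equal(net_od(40000, 40000), 0)
  expect_equal(net_od(40000, 4000), 1)
  expect_equal(net_od(40000, 20000), 0.30103, tolerance = 1e-5)
  expect_error(net_od(0, 100), "positive")
  # additivity: od(a,b) + od(b,c) = od(a,c)
  expect_equal(net_od(40000, 21000) + net_od(21000, 9000), net_od(40000, 9000))
})

test_that("cubic calibration recovers an exact cubic and rejects bad designs", {
  n <- c(0, 0.1, 0.25, 0.4, 0.55, 0.7)
  truth_cf <- c(0.05, 9, 3, 2)
  d <- truth_cf[1] + truth_cf[2] * n + truth_cf[3] * n^2 + truth_cf[4] * n^3
  cc <- fit_calibration(d, n)
  expect_equal(cc$coefficients, truth_cf, tolerance = 1e-9)

  expect_error(fit_calibration(d[1:3], n[1:3]), "rank-deficient")
  expect_error(fit_calibration(d[1:4], n[1:4]), "at least 5")
  expect_error(fit_calibration(c(0, 2, 4, 6, 5, 3), n),
               class = "breathe4d_calibration_monotone")
})

test_that("noiseless film response round-trips within 1% of the prescription", {
  truth <- film_truth()
  cal <- make_calibration_data(noise_frac = 0, seed = 1)
  curve <- fit_calibration(cal$dose_gy, cal$net_od)
  dose <- dose_plane(matrix(seq(0.5, 7.5, length.out = 25), 5, 5), 1:5, 1:5)
  scan <- simulate_film_response(dose, truth, noise_frac = 0)
  back <- scan_to_dose(scan, curve)
  expect_lt(max(abs(back$values - dose$values)), 0.01 * 6)
})

test_that("declared 0.3% scanner noise propagates as expected", {
  truth <- film_truth()
  curve <- fix_calibration_curve()
  # PV coefficient of variation close to the configured noise fraction
  dose <- dose_plane(matrix(3, 60, 60), 1:60, 1:60)
  scan <- simulate_film_response(dose, truth, noise_frac = 0.003, seed = 8)
  cv <- sd(scan$values) / mean(scan$values)
  expect_lt(abs(cv - 0.003) / 0.003, 0.2)

  # per-pixel dose error SD below 1.5% of the prescription at the Dp level
  dose6 <- dose_plane(matrix(6, 60, 60), 1:60, 1:60)
  meas <- scan_to_dose(simulate_film_response(dose6, truth, noise_frac = 0.003, seed = 9),
                       curve)
  expect_lt(sd(meas$values), 0.015 * 6)
  expect_lt(abs(mean(meas$values) - 6), 0.02 * 6)

  # calibration fitted under noise tracks the generative curve within 2% of Dp
  dd <- seq(0, 8, by = 0.25)
  ideal <- dose_plane(matrix(dd, length(dd), 1), seq_along(dd), 1)
  rt <- scan_to_dose(simulate_film_response(ideal, truth, noise_frac = 0), curve)
  expect_lt(max(abs(rt$values - dd)), 0.02 * 6)
})

test_that("film model is monotone, deterministic and range-checked", {
  truth <- film_truth()
  d <- dose_plane(matrix(c(0, 2, 4, 6), 2, 2), 1:2, 1:2)
  s0 <- simulate_film_response(d, truth, noise_frac = 0)
  expect_true(all(order(-s0$values) == order(d$values)))
  expect_equal(simulate_film_response(dose_plane(matrix(0, 2, 2), 1:2, 1:2),
                                      truth, noise_frac = 0)$values,
               matrix(40000, 2, 2))
  a <- simulate_film_response(d, truth, seed = 3)
  b <- simulate_film_response(d, truth, seed = 3)
  expect_identical(a$values, b$values)
  expect_error(simulate_film_response(dose_plane(matrix(20, 2, 2), 1:2, 1:2), truth),
               "working range")
})

test_that("film scans round-trip through CSV", {
  d <- dose_plane(matrix(runif(20, 0, 5), 4, 5), seq(0, 1.5, 0.5), seq(0, 2, 0.5))
  scan <- simulate_film_response(d, film_truth(), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_scan_csv(scan, f)
  back <- read_scan_csv(f)
  expect_equal(back$values, scan$values, tolerance = 1e-6)
  expect_equal(back$pv_bg, scan$pv_bg)
})

test_that("tidy and glance summarize a calibration fit", {
  cc <- fix_calibration_curve()
  td <- tidy(cc)
  expect_equal(nrow(td), 4)
  gl <- glance(cc)
  expect_equal(gl$n, 9)
  expect_lt(gl$max_abs_residual_gy, 0.1)
})

test_that("calibration curves round-trip through JSON", {
  cc <- fix_calibration_curve()
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cc, f)
  back <- read_calibration_json(f)
  expect_equal(back$coefficients, cc$coefficients, tolerance = 1e-12)
  expect_equal(back$range, cc$range, tolerance = 1e-12)
})
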