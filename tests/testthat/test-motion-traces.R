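test_that("regular trace matches the sinusoidal motion model", {
  tr <- generate_regular(sinusoid_params(15, 4), duration = 60)
  expect_equal(diff(range(tr$displacement_mm)), 30)
  expect_equal(tr$displacement_mm[1], -15)  # phase 0 = end-inhale at -A
  # peak speed from the sampled trace agrees with the analytic formula
  v <- diff(tr$displacement_mm) * attr(tr, "sampling_rate")
  expect_equal(max(abs(v)), 2 * pi * 15 / 4, tolerance = 0.01)
})

test_that("phase velocity formula evaluates and is antisymmetric", {
  p <- sinusoid_params(15, 4)
  expect_equal(abs(phase_velocity(25, p)), 23.56, tolerance = 0.001)
  expect_equal(phase_velocity(0, p), 0)
  expect_equal(phase_velocity(50, p), 0)
  ph <- seq(1, 99, by = 1)
  expect_equal(phase_velocity(ph, p), -phase_velocity(100 - ph, p))
  expect_error(phase_velocity(120, p), "0, 100")
})

test_that("short traces and low sampling rates are rejected", {
  expect_error(generate_regular(sinusoid_params(15, 4), duration = 3),
               class = "breathe4d_short_trace")
  expect_error(generate_regular(sinusoid_params(15, 4), duration = 60, rate = 10),
               "20 Hz")
})

test_that("cycle detection recovers boundaries of regular and irregular traces", {
  tr <- generate_regular(sinusoid_params(15, 4), duration = 30)
  b <- detect_cycles(tr)
  expect_true(all(abs(diff(b) - 4) <= 1 / attr(tr, "sampling_rate") + 1e-12))

  # irregular: detected boundaries agree with the generator's own records
  si <- generate_irregular(breathing_spec("S-I", seed = 3), duration = 60)
  b2 <- detect_cycles(si)
  gen <- attr(si, "cycles")$start
  interior <- gen[gen > 1 & gen < max(si$time_s) - 1]
  nearest <- vapply(interior, function(g) min(abs(b2 - g)), numeric(1))
  expect_true(all(nearest <= 1 / attr(si, "sampling_rate") + 1e-9))

  flat <- flat_trace(20)
  expect_error(detect_cycles(flat), class = "breathe4d_no_cycles")
})

test_that("trace statistics reproduce the configured class parameters", {
  reg <- trace_stats(generate_regular(sinusoid_params(15, 4), duration = 60))
  expect_equal(reg$range_mean, 30, tolerance = 1e-3)
  expect_equal(reg$range_sd, 0, tolerance = 1e-6)
  expect_equal(reg$period_mean, 4, tolerance = 1e-6)
  expect_equal(reg$period_sd, 0, tolerance = 1e-6)

  si <- trace_stats(generate_irregular(breathing_spec("S-I", seed = 7), 120))
  expect_lt(abs(si$range_mean - 18.6), 0.3)
  expect_lt(abs(si$period_mean - 2.83), 0.10)

  ai <- trace_stats(generate_irregular(breathing_spec("A-I", seed = 7), 240))
  expect_gte(ai$range_sd / ai$range_mean, 0.10)
})

test_that("long traces recover base range and period within 2 SE per class", {
  for (cl in c("S-I", "A-I", "P-I", "P+A-I")) {
    spec <- breathing_spec(cl, seed = 1)
    dur <- ceiling(spec$base_period * 60)  # >= 50 cycles
    st <- trace_stats(generate_irregular(spec, duration = dur))
    expect_gte(st$n_cycles, 50)
    se_r <- st$range_sd / sqrt(st$n_cycles)
    se_p <- st$period_sd / sqrt(st$n_cycles)
    expect_lt(abs(st$range_mean - spec$base_range), 2 * se_r + 1e-9,
              label = sprintf("%s range_mean", cl))
    expect_lt(abs(st$period_mean - spec$base_period), 2 * se_p + 1e-9,
              label = sprintf("%s period_mean", cl))
  }
})

test_that("irregular generator is deterministic and degenerates to the sinusoid", {
  a <- generate_irregular(breathing_spec("P+A-I", seed = 5), 60)
  b <- generate_irregular(breathing_spec("P+A-I", seed = 5), 60)
  expect_identical(a$displacement_mm, b$displacement_mm)

  z <- generate_irregular(breathing_spec("S-I", base_range = 30, base_period = 4,
                                         range_jitter_frac = 0, period_jitter_frac = 0),
                          duration = 20)
  r <- generate_regular(sinusoid_params(15, 4), duration = 20)
  expect_equal(z$displacement_mm, r$displacement_mm, tolerance = 1e-12)
})

test_that("retrospective phase interpolates linearly within cycles", {
  tr <- generate_regular(sinusoid_params(15, 4), duration = 30)
  b <- detect_cycles(tr)
  expect_equal(phase_at_time(b[1], b), 0)
  expect_equal(phase_at_time(b[1] + 1, b), 25)  # T/4 into a 4 s cycle
  expect_error(phase_at_time(max(b) + 1, b), class = "breathe4d_phase_range")

  si <- generate_irregular(breathing_spec("S-I", seed = 9), 60)
  b2 <- detect_cycles(si)
  t_mid <- (b2[3] + b2[4]) / 2
  expect_equal(phase_at_time(t_mid, b2),
               100 * (t_mid - b2[3]) / (b2[4] - b2[3]))
})

test_that("trace CSV round-trips and tolerates comment lines", {
  tr <- generate_regular(sinusoid_params(15, 4), duration = 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  txt <- c("# surrogate trace", readLines(f))
  writeLines(txt, f)
  back <- read_trace_csv(f)
  expect_equal(back$displacement_mm, tr$displacement_mm)
  expect_equal(attr(back, "sampling_rate"), 25, tolerance = 1e-6)
})
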