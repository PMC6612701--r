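test_that("identical planes give zero gamma and full passing", {
  x <- seq(0, 10, 0.5); y <- seq(0, 10, 0.5)
  d <- dose_plane(matrix(6, length(x), length(y)), x, y)
  roi <- matrix(TRUE, length(x), length(y))
  gm <- gamma_2d(d, d, gamma_criteria(norm = 6), roi)
  expect_true(all(gm$gamma[gm$roi] == 0))
  expect_equal(passing_rate(gm), 100)
})

test_that("a 1 mm shift of a 5%/mm ramp gives the closed-form gamma", {
  x <- seq(0, 40, 0.5); y <- seq(0, 20, 0.5)
  norm <- 6
  ramp <- function(xx) 3 + 0.05 * norm * xx   # 5% of norm per mm along x
  ref <- dose_plane(matrix(ramp(x), length(x), length(y)), x, y)
  ev <- dose_plane(matrix(ramp(x - 1), length(x), length(y)), x, y)
  roi <- matrix(FALSE, length(x), length(y))
  roi[30:50, 15:25] <- TRUE  # interior, away from edges
  gm <- gamma_2d(ref, ev, gamma_criteria(dose_tol = 3, dta = 1, norm = norm), roi)
  expect_equal(max(gm$gamma, na.rm = TRUE), 5 / sqrt(34), tolerance = 0.01)
  expect_equal(min(gm$gamma, na.rm = TRUE), 5 / sqrt(34), tolerance = 0.01)
})

test_that("gamma engine matches the exhaustive brute-force oracle", {
  set.seed(99)
  x <- seq(0, 10, 0.5); y <- seq(0, 10, 0.5)
  crit <- gamma_criteria(dose_tol = 3, dta = 1, norm = 6, step = 0.2, cutoff = 0)
  roi <- matrix(FALSE, length(x), length(y))
  roi[8:14, 8:14] <- TRUE
  for (k in 1:20) {
    base <- matrix(rnorm(length(x) * length(y), 5, 0.6), length(x))
    sm <- function(m) (m + rbind(m[-1, ], m[nrow(m), ]) + cbind(m[, -1], m[, ncol(m)])) / 3
    ref <- dose_plane(pmax(sm(base), 0), x, y)
    ev <- dose_plane(pmax(sm(base) + matrix(rnorm(length(base), 0, 0.15), nrow(base)), 0), x, y)
    gm <- gamma_2d(ref, ev, crit, roi)
    or <- oracle_gamma(ref, ev, crit, roi)
    expect_equal(gm$gamma[gm$roi], or[gm$roi], tolerance = 1e-9)
  }
})

test_that("loosening criteria never lowers the passing rate", {
  set.seed(7)
  x <- seq(0, 15, 0.5); y <- seq(0, 15, 0.5)
  m <- matrix(5 + sin(outer(x, y) / 8), length(x), length(y))
  ref <- dose_plane(m, x, y)
  ev <- dose_plane(m * (1 + matrix(rnorm(length(m), 0, 0.03), nrow(m))), x, y)
  roi <- matrix(TRUE, length(x), length(y))
  tight <- passing_rate(gamma_2d(ref, ev, gamma_criteria(2, 1, 6), roi))
  loose_dose <- passing_rate(gamma_2d(ref, ev, gamma_criteria(4, 1, 6), roi))
  loose_dta <- passing_rate(gamma_2d(ref, ev, gamma_criteria(2, 2, 6, step = 0.2), roi))
  expect_gte(loose_dose, tight)
  expect_gte(loose_dta, tight)
})

test_that("a rigid sub-DTA shift passes everywhere", {
  x <- seq(0, 30, 0.5); y <- seq(0, 30, 0.5)
  f <- function(xx, yy) 4 + 2 * exp(-((xx - 15)^2 + (yy - 15)^2) / 60)
  ref <- dose_plane(outer(x, y, f), x, y)
  ev <- dose_plane(outer(x - 0.8, y, f), x, y)
  roi <- matrix(FALSE, length(x), length(y))
  roi[20:40, 20:40] <- TRUE
  gm <- gamma_2d(ref, ev, gamma_criteria(3, 1, 6), roi)
  expect_equal(passing_rate(gm), 100)
})

test_that("ROI handling and low-dose cutoff behave as configured", {
  x <- seq(0, 10, 0.5); y <- seq(0, 10, 0.5)
  vals <- matrix(0.1, length(x), length(y))   # below 10% of 6 Gy
  vals[5:10, 5:10] <- 6
  d <- dose_plane(vals, x, y)
  roi <- matrix(TRUE, length(x), length(y))
  gm <- gamma_2d(d, d, gamma_criteria(norm = 6, cutoff = 10), roi)
  expect_equal(sum(gm$roi), 36)  # only the high-dose block is scored
  expect_error(gamma_2d(d, d, gamma_criteria(), matrix(FALSE, length(x), length(y))),
               "ROI")
})

test_that("target ROI dilates the GTV projection monotonically", {
  gtv <- fix_static_gtv()
  x <- seq(-20, 20, 0.5); y <- seq(-25, 25, 0.5)
  r0 <- target_roi(gtv, x, y, 0)
  r2 <- target_roi(gtv, x, y, 2)
  r4 <- target_roi(gtv, x, y, 4)
  expect_identical(r0, mask_projection(gtv, x, y))
  expect_true(all(r2[r0]) && all(r4[r2]))
  expect_gt(sum(r4), sum(r2))
})

test_that("paired comparison computes the textbook t statistic", {
  pc <- paired_comparison(c(11, 12, 13), c(10, 10, 10))
  expect_equal(pc$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_false(pc$degenerate)

  deg <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(paired_comparison(1, 1), "length")
})

test_that("gamma map tidiers expose per-point and summary views", {
  x <- seq(0, 5, 0.5); y <- seq(0, 5, 0.5)
  d <- dose_plane(matrix(6, length(x), length(y)), x, y)
  gm <- gamma_2d(d, d, gamma_criteria(norm = 6), matrix(TRUE, length(x), length(y)))
  td <- tidy(gm)
  expect_true(all(td$pass))
  gl <- glance(gm)
  expect_equal(gl$passing_rate, 100)
  expect_equal(gl$n_points, sum(gm$roi))
})
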