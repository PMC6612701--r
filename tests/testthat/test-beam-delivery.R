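test_that("plans meet both coverage constraints on the PTV", {
  ptv <- expand_margin(fix_static_gtv(), 5)
  for (tech in c("sliding_window", "arc")) {
    plan <- build_plan(ptv, plan_spec(tech))
    roi <- mask_projection(ptv, plan$x, plan$y)
    cov <- coverage_metrics(plan$planned, roi, dp = 6)
    expect_gte(cov$v_dp, 95)
    expect_gte(cov$v_09dp, 99)
    expect_lte(max(plan$planned$values), plan$spec$hotspot_cap * 6 + 1e-6)
  }
  expect_error(build_plan(ptv, plan_spec(margin_cap = 0, hotspot_cap = 1.0)),
               class = "breathe4d_plan_coverage")
})

test_that("static delivery reproduces the planned plane for both techniques", {
  ptv <- expand_margin(fix_static_gtv(), 5)
  for (tech in c("sliding_window", "arc")) {
    plan <- build_plan(ptv, plan_spec(tech))
    del <- deliver(plan, flat_trace(plan$beam_on_time + 20))
    rel <- abs(del$values - plan$planned$values) / max(plan$planned$values)
    expect_lt(max(rel), 0.005)
  }
})

test_that("uniform and zero dose planes give trivial coverage", {
  x <- seq(0, 10, 0.5); y <- seq(0, 10, 0.5)
  roi <- matrix(TRUE, length(x), length(y))
  u <- dose_plane(matrix(6, length(x), length(y)), x, y)
  expect_equal(coverage_metrics(u, roi, 6)$v_dp, 100)
  z <- dose_plane(matrix(0, length(x), length(y)), x, y)
  expect_equal(coverage_metrics(z, roi, 6)$v_dp, 0)
})

test_that("gating of a regular trace gives a 40% duty cycle in the window", {
  tr <- generate_regular(sinusoid_params(15, 4), duration = 120)
  sig <- gating_signal(tr, c(30, 70), latency = 0)
  expect_equal(attr(sig, "duty"), 0.4, tolerance = 0.01)

  # retrospective phase during beam-on stays within the window
  b <- detect_cycles(tr)
  expect_lt(misgating_fraction(tr, sig), 0.02)
})

test_that("irregular periods cause mis-gating of the prospective signal", {
  tr <- generate_irregular(breathing_spec("P-I", seed = 4), duration = 240)
  sig <- gating_signal(tr, c(30, 70), latency = 0, position_veto = FALSE)
  expect_gt(misgating_fraction(tr, sig), 0.02)
  # the position veto reduces how far beam-on positions stray, never below 0
  sigv <- gating_signal(tr, c(30, 70), latency = 0)
  expect_lte(attr(sigv, "duty"), attr(sig, "duty") + 1e-9)
})

test_that("delivered dose integral is conserved under rigid motion", {
  ptv <- expand_margin(fix_static_gtv(), 5)
  plan <- build_plan(ptv, plan_spec("sliding_window"))
  for (cl in c("regular", "S-I", "P+A-I")) {
    tr <- if (cl == "regular") {
      generate_regular(sinusoid_params(15, 4), plan$beam_on_time + 30)
    } else {
      generate_irregular(breathing_spec(cl, seed = 6), plan$beam_on_time + 30)
    }
    del <- deliver(plan, tr)
    expect_lt(abs(sum(del$values) / sum(plan$planned$values) - 1), 0.01,
              label = sprintf("fluence conservation (%s)", cl))
  }
})

test_that("gated delivery agrees with the plan better than nongated", {
  spec <- fix_phantom()
  tr_img <- generate_irregular(breathing_spec("P+A-I", seed = 11), 90)
  pvs <- simulate_4dct(spec, tr_img, acquisition_config(n_phases = 10))
  proj <- project(pvs, "AIP")
  itv_g <- segment_projection_itv(proj, pvs, c(30, 70))
  itv_ng <- segment_projection_itv(proj, pvs, c(0, 100))
  plan_g <- build_plan(expand_margin(itv_g, 5),
                       plan_spec("sliding_window", gating_window = c(30, 70),
                                 gate_corridor = gate_corridor_from_itv(itv_g)))
  plan_ng <- build_plan(expand_margin(itv_ng, 5), plan_spec("sliding_window"))
  gtv <- fix_static_gtv()
  rate <- function(plan, trace) {
    del <- deliver(plan, trace)
    roi <- target_roi(gtv, plan$x, plan$y, 2)
    passing_rate(gamma_2d(plan$planned, del, gamma_criteria(norm = 6), roi))
  }
  tr_g <- generate_irregular(breathing_spec("P+A-I", seed = 21),
                             ceiling(plan_g$beam_on_time / 0.12) + 120)
  tr_ng <- generate_irregular(breathing_spec("P+A-I", seed = 21),
                              ceiling(plan_ng$beam_on_time) + 60)
  expect_gt(rate(plan_g, tr_g), rate(plan_ng, tr_ng))
})

test_that("exhausted traces abort the delivery", {
  plan <- build_plan(expand_margin(fix_static_gtv(), 5), plan_spec())
  expect_error(deliver(plan, flat_trace(30)), class = "breathe4d_short_trace")
})

test_that("dose planes round-trip through CSV", {
  d <- dose_plane(matrix(runif(36, 0, 6), 6, 6), seq(0, 2.5, 0.5), seq(0, 2.5, 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(d, f)
  back <- read_dose_csv(f)
  expect_equal(back$values, d$values, tolerance = 1e-9)
})
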