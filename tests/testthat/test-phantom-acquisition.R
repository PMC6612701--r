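test_that("rendered sphere matches the analytic volume and centroid", {
  spec <- fix_phantom()
  m <- fix_static_gtv()
  # voxel-center counting of a sphere whose surface passes through voxel
  # centers under-counts slightly; 2% bounds the rasterization bias
  expect_lt(abs(variation(mask_volume_cm3(m), sphere_volume_cm3(10))), 2)
  expect_true(all(abs(mask_centroid(m) - c(0, 0, 0)) <= 0.5))

  m7 <- segment_target(render_phantom(spec, 7))
  expect_true(all(abs(mask_centroid(m7) - c(0, 7, 0)) <= 0.5))

  a <- render_phantom(spec, 3, noise_sd = 20, seed = 4)
  b <- render_phantom(spec, 3, noise_sd = 20, seed = 4)
  expect_identical(a$values, b$values)

  expect_error(render_phantom(spec, 30), class = "breathe4d_geometry")
})

test_that("static CT volumetry stays within 2.5% despite imaging noise", {
  spec <- fix_phantom()
  ct <- simulate_static_ct(spec, acquisition_config(seed = 1))
  m <- segment_target(ct)
  expect_lt(abs(variation(mask_volume_cm3(m), sphere_volume_cm3(10))), 2.5)

  inside <- fix_static_gtv()$values
  hu <- ct$values[inside]
  se <- 20 / sqrt(sum(inside))
  expect_lt(abs(mean(hu) - mean(fix_static_noiseless()$values[inside])), 3 * se + 1)
})

test_that("zero-motion 4D CT reproduces the static volume in every phase", {
  spec <- fix_phantom()
  cfg <- acquisition_config(n_phases = 10, hu_noise_sd = 0)
  pvs <- simulate_4dct(spec, flat_trace(90), cfg)
  expect_length(pvs$volumes, 10)
  static <- render_phantom(spec, 0)
  for (v in pvs$volumes) expect_equal(v$values, static$values)
})

test_that("acquisition latency shifts fast-moving phases and is recoverable", {
  spec <- fix_phantom()
  tr <- fix_regular_trace()
  pvs <- simulate_4dct(spec, tr, acquisition_config(n_phases = 20, time_delay = 0.14))
  tb <- phase_position_table(pvs, sinusoid_params(15, 4))

  dev25 <- tb$deviation_mm[which.min(abs(tb$phase - 25))]
  expect_gte(dev25, 3.0)
  expect_lte(dev25, 3.8)
  # among the tabulated phases, deviations peak at the fastest (25% and 75%)
  tab <- tb[tb$phase %in% c(0, 25, 50, 75), ]
  top2 <- tab$phase[order(-abs(tab$deviation_mm))][1:2]
  expect_setequal(top2, c(25, 75))
  expect_lt(abs(estimate_time_delay(tb) - 0.14), 0.25)

  # latency recovery across configured delays (one image-sampling interval)
  for (delay in c(0, 0.2)) {
    p10 <- simulate_4dct(spec, tr, acquisition_config(n_phases = 10, time_delay = delay))
    est <- estimate_time_delay(phase_position_table(p10))
    expect_lt(abs(est - delay), 0.25)
  }
})

test_that("phase-0 position and 10-vs-20-phase agreement hold for regular motion", {
  spec <- fix_phantom()
  tr <- fix_regular_trace()
  p0 <- simulate_4dct(spec, tr, acquisition_config(n_phases = 10, time_delay = 0))
  tb0 <- phase_position_table(p0)
  expect_lt(abs(tb0$measured_mm[tb0$phase == 0] + 15), 0.5)

  p20 <- simulate_4dct(spec, tr, acquisition_config(n_phases = 20))
  tb10 <- phase_position_table(fix_regular_pvs10())
  tb20 <- phase_position_table(p20)
  shared <- intersect(tb10$phase, tb20$phase)
  d10 <- tb10$measured_mm[match(shared, tb10$phase)]
  d20 <- tb20$measured_mm[match(shared, tb20$phase)]
  expect_true(all(abs(d10 - d20) <= 1))
})

test_that("irregular breathing produces measurable mis-binning", {
  spec <- fix_phantom()
  cfg <- acquisition_config(n_phases = 10)
  reg_sd <- mean(misbinning_stats(fix_regular_pvs10())$center_sd_mm)
  for (cl in c("P-I", "P+A-I")) {
    tr <- generate_irregular(breathing_spec(cl, seed = 2), 90)
    pvs <- simulate_4dct(spec, tr, cfg)
    irr_sd <- mean(misbinning_stats(pvs)$center_sd_mm)
    expect_gt(irr_sd, reg_sd)
  }
})

test_that("too-short traces are rejected with the required duration", {
  spec <- fix_phantom()
  tr <- generate_regular(sinusoid_params(15, 4), duration = 20)
  expect_error(simulate_4dct(spec, tr, acquisition_config()),
               class = "breathe4d_short_trace")
})

test_that("volumes survive a NIfTI round trip", {
  v <- fix_static_noiseless()
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  back <- read_volume(f)
  expect_equal(back$values, v$values, tolerance = 1e-6)
  expect_equal(back$spacing, v$spacing)
})
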