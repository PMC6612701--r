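# shared fixtures, computed lazily and cached for the whole run
.fix <- new.env(parent = emptyenv())

fix_cached <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

fix_phantom <- function() fix_cached("phantom", phantom_spec())

fix_static_noiseless <- function() {
  fix_cached("static_noiseless", render_phantom(fix_phantom(), 0))
}

fix_static_gtv <- function() {
  fix_cached("static_gtv", segment_target(fix_static_noiseless()))
}

fix_regular_trace <- function() {
  fix_cached("reg_trace", generate_regular(sinusoid_params(15, 4), duration = 90))
}

# 10-phase 4D CT of the regular trace with the default 0.14 s latency
fix_regular_pvs10 <- function() {
  fix_cached("reg_pvs10", simulate_4dct(fix_phantom(), fix_regular_trace(),
                                        acquisition_config(n_phases = 10)))
}

fix_calibration_curve <- function() {
  fix_cached("curve", {
    cal <- make_calibration_data(seed = 42L)
    fit_calibration(cal$dose_gy, cal$net_od)
  })
}

# constant-position trace long enough for a static delivery
flat_trace <- function(duration, value = 0, rate = 25) {
  tt <- seq(0, duration, by = 1 / rate)
  breathe4d:::new_motion_trace(tt, rep(value, length(tt)), rate, "static")
}

sphere_volume_cm3 <- function(r) 4 / 3 * pi * r^3 / 1000
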