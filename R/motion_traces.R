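#' Sinusoidal breathing parameters
#'
#' Parameters of the regular breathing model: a sinusoid with amplitude `A`
#' (half the peak-to-trough longitudinal excursion, mm) and period `T` (s).
#' The study's regular pattern is `A = 15` mm, `T = 4` s, i.e. a longitudinal
#' range of plus/minus 15 mm.
#'
#' @param A Amplitude in mm (half peak-to-trough). Must be > 0.
#' @param T Breathing period in seconds. Must be > 0.
#' @return An object of class `sinusoid_params`.
#' @export
#' @examples
#' sinusoid_params(15, 4)
sinusoid_params <- function(A = 15, T = 4) {
  assert_scalar_num(A, "A", positive = TRUE)
  assert_scalar_num(T, "T", positive = TRUE)
  structure(list(A = A, T = T), class = "sinusoid_params")
}

# Table-driven class defaults: mean range (mm), mean period (s) and per-cycle
# jitter fractions calibrated so the generated cycle SDs reproduce the
# reported irregular-pattern statistics.
.breathing_class_defaults <- list(
  "regular" = list(base_range = 30,   base_period = 4,    range_jitter_frac = 0,     period_jitter_frac = 0),
  "S-I"     = list(base_range = 18.6, base_period = 2.83, range_jitter_frac = 0.016, period_jitter_frac = 0.035),
  "A-I"     = list(base_range = 16.9, base_period = 3.47, range_jitter_frac = 0.13,  period_jitter_frac = 0.10),
  "P-I"     = list(base_range = 17.8, base_period = 4.35, range_jitter_frac = 0.04,  period_jitter_frac = 0.18),
  "P+A-I"   = list(base_range = 13.3, base_period = 3.50, range_jitter_frac = 0.23,  period_jitter_frac = 0.31)
)

#' Breathing model specification
#'
#' Defines one of the study's motion classes: `regular` (pure sinusoid),
#' `S-I` (slightly irregular), `A-I` (amplitude irregular), `P-I` (period
#' irregular) or `P+A-I` (period and amplitude irregular). Per-cycle
#' peak-to-trough range and period are drawn from normal distributions around
#' the base values with the given jitter fractions; the class defaults
#' reproduce the reported mean +/- SD of each pattern.
#'
#' @param motion_class One of `"regular"`, `"S-I"`, `"A-I"`, `"P-I"`, `"P+A-I"`.
#' @param base_range Mean peak-to-trough range in mm (default from class).
#' @param base_period Mean breathing period in s (default from class).
#' @param range_jitter_frac Per-cycle SD of range as a fraction of `base_range`.
#' @param period_jitter_frac Per-cycle SD of period as a fraction of `base_period`.
#' @param seed Integer seed making the generated trace reproducible.
#' @return An object of class `breathing_spec`.
#' @export
breathing_spec <- function(motion_class = c("S-I", "A-I", "P-I", "P+A-I", "regular"),
                           base_range = NULL, base_period = NULL,
                           range_jitter_frac = NULL, period_jitter_frac = NULL,
                           seed = 1L) {
  motion_class <- match.arg(motion_class)
  d <- .breathing_class_defaults[[motion_class]]
  spec <- list(
    motion_class = motion_class,
    base_range = base_range %||% d$base_range,
    base_period = base_period %||% d$base_period,
    range_jitter_frac = range_jitter_frac %||% d$range_jitter_frac,
    period_jitter_frac = period_jitter_frac %||% d$period_jitter_frac,
    seed = as.integer(seed)
  )
  assert_scalar_num(spec$base_range, "base_range", positive = TRUE)
  assert_scalar_num(spec$base_period, "base_period", positive = TRUE)
  assert_scalar_num(spec$range_jitter_frac, "range_jitter_frac", nonneg = TRUE)
  assert_scalar_num(spec$period_jitter_frac, "period_jitter_frac", nonneg = TRUE)
  structure(spec, class = "breathing_spec")
}

new_motion_trace <- function(time_s, displacement_mm, rate, label, cycles = NULL) {
  out <- tibble(time_s = time_s, displacement_mm = displacement_mm)
  attr(out, "sampling_rate") <- rate
  attr(out, "label") <- label
  attr(out, "cycles") <- cycles
  class(out) <- c("motion_trace", class(out))
  out
}

#' Generate a regular (sinusoidal) breathing trace
#'
#' Longitudinal target position relative to mid-range, sampled uniformly.
#' The phase convention places phase 0% at the end-inhale extreme, where the
#' target sits at `-A` mm (most caudal), so
#' `displacement(t) = -A * cos(2 * pi * t / T)`.
#'
#' @param params A [sinusoid_params()] object.
#' @param duration Trace length in seconds; must cover at least one period.
#' @param rate Sampling rate in Hz (>= 20; default 25, surrogate-camera-like).
#' @return A `motion_trace` tibble with columns `time_s`, `displacement_mm`.
#' @export
#' @examples
#' tr <- generate_regular(sinusoid_params(15, 4), duration = 12)
#' range(tr$displacement_mm)  # +/- 15 mm
generate_regular <- function(params = sinusoid_params(), duration = 60, rate = 25) {
  stopifnot(inherits(params, "sinusoid_params"))
  assert_scalar_num(duration, "duration", positive = TRUE)
  assert_scalar_num(rate, "rate", positive = TRUE)
  if (duration < params$T) {
    stop_breathe4d(sprintf(
      "`duration` (%.3g s) must cover at least one breathing period (T = %.3g s)",
      duration, params$T), class = "breathe4d_short_trace")
  }
  if (rate < 20) stop_breathe4d("`rate` must be at least 20 Hz")
  t <- seq(0, duration, by = 1 / rate)
  d <- -params$A * cospi(2 * t / params$T)
  new_motion_trace(t, d, rate, "regular")
}

#' Generate an irregular breathing trace
#'
#' Draws a per-cycle peak-to-trough range and period around the class base
#' values (truncated normal; non-positive draws are redrawn and counted), then
#' synthesizes the trace as cosine half-cycles joined at the turning points so
#' the waveform is continuous with zero slope at every extreme. Cycle
#' boundaries sit at the end-inhale troughs (`-range/2`); the exhale peak of
#' cycle *i* is `+range_i/2`.
#'
#' Deterministic for a fixed `spec$seed`; the drawn per-cycle records are kept
#' in `attr(trace, "cycles")` for downstream checks.
#'
#' @param spec A [breathing_spec()].
#' @param duration Trace length in s; should cover at least 10 cycles for
#'   stable statistics (default 120 s).
#' @param rate Sampling rate in Hz.
#' @return A `motion_trace` tibble.
#' @export
generate_irregular <- function(spec, duration = 120, rate = 25) {
  stopifnot(inherits(spec, "breathing_spec"))
  assert_scalar_num(duration, "duration", positive = TRUE)
  if (duration < spec$base_period) {
    stop_breathe4d("`duration` must cover at least one breathing period",
                   class = "breathe4d_short_trace")
  }
  n_guess <- ceiling(duration / spec$base_period * 1.6) + 5L
  draws <- with_seed_if(spec$seed, {
    n_redraw <- 0L
    draw_trunc <- function(n, mean, sd) {
      v <- rnorm(n, mean, sd)
      while (any(bad <- v <= 0)) {
        n_redraw <<- n_redraw + sum(bad)
        v[bad] <- rnorm(sum(bad), mean, sd)
      }
      v
    }
    ranges <- draw_trunc(n_guess, spec$base_range, spec$range_jitter_frac * spec$base_range)
    periods <- draw_trunc(n_guess, spec$base_period, spec$period_jitter_frac * spec$base_period)
    list(ranges = ranges, periods = periods, n_redraw = n_redraw)
  })
  starts <- cumsum(c(0, draws$periods))[seq_len(n_guess)]
  keep <- which(starts <= duration)
  n_cyc <- max(keep) + 1L  # one spare cycle past the requested duration
  R <- draws$ranges[seq_len(n_cyc)]
  P <- draws$periods[seq_len(n_cyc)]
  # knots: trough_i (-R_i/2) -> peak_i (+R_i/2) -> trough_{i+1} (-R_{i+1}/2)
  kt <- numeric(2L * n_cyc + 1L)
  kv <- numeric(2L * n_cyc + 1L)
  t0 <- cumsum(c(0, P))
  kt[seq(1L, 2L * n_cyc + 1L, by = 2L)] <- t0
  kt[seq(2L, 2L * n_cyc, by = 2L)] <- t0[seq_len(n_cyc)] + P / 2
  kv[seq(1L, 2L * n_cyc - 1L, by = 2L)] <- -R / 2
  kv[2L * n_cyc + 1L] <- -R[n_cyc] / 2  # closing trough reuses last cycle's range
  kv[seq(2L, 2L * n_cyc, by = 2L)] <- R / 2
  t <- seq(0, duration, by = 1 / rate)
  seg <- findInterval(t, kt, rightmost.closed = TRUE)
  seg <- pmin(seg, length(kt) - 1L)
  tau <- (t - kt[seg]) / (kt[seg + 1L] - kt[seg])
  d <- kv[seg] + (kv[seg + 1L] - kv[seg]) * (1 - cospi(tau)) / 2
  cycles <- tibble(start = t0[seq_len(n_cyc)], period = P, range = R)
  tr <- new_motion_trace(t, d, rate, spec$motion_class, cycles = cycles)
  attr(tr, "n_redraw") <- draws$n_redraw
  tr
}

#' Detect breathing-cycle boundaries
#'
#' Cycle boundaries are the end-inhale extremes of the trace (the most caudal
#' target positions, where retrospective phase is 0%), found as local maxima
#' of the inhale excursion (`-displacement`) with prominence at least
#' `prominence_frac` of the trace's total range.
#'
#' @param trace A `motion_trace`.
#' @param prominence_frac Minimum peak prominence as a fraction of range.
#' @return Strictly increasing numeric vector of boundary times (s).
#' @export
detect_cycles <- function(trace, prominence_frac = 0.25) {
  stopifnot(is.data.frame(trace), all(c("time_s", "displacement_mm") %in% names(trace)))
  x <- -trace$displacement_mm
  n <- length(x)
  rng <- diff(range(x))
  if (!is.finite(rng) || rng <= 0) {
    stop_breathe4d("no breathing cycles found: trace has no peaks",
                   class = "breathe4d_no_cycles")
  }
  i <- 2:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  prom <- vapply(cand, function(j) {
    h <- x[j]
    left <- x[seq_len(j - 1L)]
    higher_l <- which(left > h)
    base_l <- min(left[seq.int(if (length(higher_l)) max(higher_l) else 1L, j - 1L)])
    right <- x[seq.int(j + 1L, n)]
    higher_r <- which(right > h)
    base_r <- min(right[seq_len(if (length(higher_r)) min(higher_r) else length(right))])
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= prominence_frac * rng]
  if (length(keep) < 2L) {
    stop_breathe4d("fewer than 2 cycle boundaries detected: insufficient data",
                   class = "breathe4d_no_cycles")
  }
  trace$time_s[keep]
}

#' Per-cycle breathing statistics
#'
#' Computes, for each detected cycle, the peak-to-trough range (exhale peak
#' minus the end-inhale trough that starts the cycle) and the boundary-to-
#' boundary period, and aggregates them as mean +/- SD.
#'
#' @param trace A `motion_trace`.
#' @param boundaries Optional pre-computed cycle boundary times.
#' @return A one-row tibble: `range_mean`, `range_sd`, `period_mean`,
#'   `period_sd`, `n_cycles`.
#' @export
trace_stats <- function(trace, boundaries = NULL) {
  b <- boundaries %||% detect_cycles(trace)
  if (length(b) < 3L) {
    stop_breathe4d("need at least 2 full cycles for statistics",
                   class = "breathe4d_no_cycles")
  }
  periods <- diff(b)
  ranges <- vapply(seq_len(length(b) - 1L), function(k) {
    in_cycle <- trace$time_s >= b[k] & trace$time_s <= b[k + 1L]
    start_val <- trace$displacement_mm[which.min(abs(trace$time_s - b[k]))]
    max(trace$displacement_mm[in_cycle]) - start_val
  }, numeric(1))
  tibble(
    range_mean = mean(ranges), range_sd = sd(ranges),
    period_mean = mean(periods), period_sd = sd(periods),
    n_cycles = length(periods)
  )
}

#' Target velocity at a breathing phase
#'
#' For a sinusoidal trace the instantaneous longitudinal velocity at phase
#' `p` (%) is `V(p) = -(2 * pi * A / T) * sin(2 * pi * p / 100)` mm/s. Its
#' magnitude peaks at phases 25% and 75% (`2 * pi * A / T`; 23.56 mm/s for the
#' regular 15 mm / 4 s pattern).
#'
#' @param p Phase in percent, in `[0, 100]`. Vectorized.
#' @param params A [sinusoid_params()].
#' @return Velocity in mm/s (negative while the target moves caudally).
#' @export
#' @examples
#' abs(phase_velocity(25, sinusoid_params(15, 4)))  # 23.56 mm/s
phase_velocity <- function(p, params = sinusoid_params()) {
  stopifnot(inherits(params, "sinusoid_params"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    stop_breathe4d("phase `p` must lie in [0, 100]")
  }
  -(2 * pi * params$A / params$T) * sinpi(2 * p / 100)
}

#' Retrospective phase at a time point
#'
#' Linear phase within the annotated cycle containing `t`: 0% at the cycle's
#' starting end-inhale boundary, growing to 100% at the next boundary.
#'
#' @param t Time(s) in seconds; each must lie in `[first boundary, last boundary)`.
#' @param boundaries Cycle boundary times from [detect_cycles()].
#' @return Phase(s) in percent, in `[0, 100)`.
#' @export
phase_at_time <- function(t, boundaries) {
  if (length(boundaries) < 2L) stop_breathe4d("need at least 2 cycle boundaries")
  if (any(t < boundaries[1L] | t >= boundaries[length(boundaries)])) {
    stop_breathe4d("time outside annotated cycles", class = "breathe4d_phase_range")
  }
  k <- findInterval(t, boundaries)
  100 * (t - boundaries[k]) / (boundaries[k + 1L] - boundaries[k])
}

#' Write / read a breathing trace as CSV
#'
#' Two columns `time_s,displacement_mm` with a header; the reader tolerates
#' comment lines starting with `#`.
#'
#' @param trace A `motion_trace`.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `motion_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble(time_s = trace$time_s, displacement_mm = trace$displacement_mm), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("time_s", "displacement_mm") %in% names(df))) {
    stop_breathe4d("trace CSV must have columns `time_s` and `displacement_mm`")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    stop_breathe4d("trace times must be uniformly increasing")
  }
  new_motion_trace(df$time_s, df$displacement_mm, 1 / mean(dt), "file")
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline labs geom_raster
#'   scale_fill_viridis_c coord_equal geom_point theme_minimal
#' @export
ggplot2::autoplot

#' Plot a breathing trace
#'
#' @param object A `motion_trace`.
#' @param boundaries Optional cycle boundary times to mark.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.motion_trace <- function(object, boundaries = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time_s, y = .data$displacement_mm)) +
    geom_line(colour = "steelblue") +
    labs(x = "time (s)", y = "longitudinal displacement (mm)",
         title = attr(object, "label")) +
    theme_minimal()
  if (!is.null(boundaries)) {
    p <- p + geom_vline(xintercept = boundaries, linetype = "dotted", colour = "grey40")
  }
  p
}

#' @importFrom rlang .data
NULL
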