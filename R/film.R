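#' Ground-truth sensitometric model for synthetic film
#'
#' The generative dose-response used to synthesize radiochromic-film scans:
#' a saturating net optical density `netOD(D) = alpha * D / (1 + beta * D)`,
#' EBT3-like in shape. The cubic netOD-to-dose calibration fitted downstream
#' is then an approximation of this truth, exactly as a measured sensitometric
#' curve is approximated in practice. The model is exactly invertible:
#' `D(netOD) = netOD / (alpha - beta * netOD)`.
#'
#' @param alpha Initial slope in 1/Gy.
#' @param beta Saturation parameter in 1/Gy.
#' @param max_dose Working-range maximum in Gy; doses above it are rejected.
#' @return An object of class `film_truth`.
#' @export
film_truth <- function(alpha = 0.12, beta = 0.05, max_dose = 12) {
  assert_scalar_num(alpha, "alpha", positive = TRUE)
  assert_scalar_num(beta, "beta", nonneg = TRUE)
  structure(list(alpha = alpha, beta = beta, max_dose = max_dose),
            class = "film_truth")
}

truth_netod <- function(truth, dose) truth$alpha * dose / (1 + truth$beta * dose)

#' Net optical density of a film pixel
#'
#' `netOD = log10(PV_bg / PV_exp)`: the background (unexposed) over exposed
#' pixel-value ratio on the 16-bit scanner scale.
#'
#' @param pv_bg,pv_exp Background and exposed pixel values (> 0). Vectorized.
#' @return netOD value(s).
#' @export
#' @examples
#' net_od(40000, 4000)   # 1
#' net_od(40000, 20000)  # 0.30103
net_od <- function(pv_bg, pv_exp) {
  if (any(pv_bg <= 0) || any(pv_exp <= 0)) {
    stop_breathe4d("pixel values must be positive")
  }
  log10(pv_bg / pv_exp)
}

#' Film scan container
#'
#' @param values Pixel-value matrix (16-bit scale).
#' @param x,y Physical grid coordinates in mm.
#' @param pv_bg Background (unexposed) pixel value.
#' @return An object of class `film_scan`.
#' @export
film_scan <- function(values, x, y, pv_bg) {
  stopifnot(is.matrix(values))
  if (any(values <= 0) || any(values > 65535)) {
    stop_breathe4d("pixel values must lie in (0, 65535]")
  }
  structure(list(values = values, x = x, y = y, pv_bg = pv_bg),
            class = "film_scan")
}

#' Simulate the film response to a dose plane
#'
#' Exposure plus scanning: `PV = pv_bg * 10^(-netOD(dose))` under the
#' ground-truth sensitometric model, with multiplicative Gaussian pixel-value
#' noise of fractional SD `noise_frac`. Deterministic for a fixed seed.
#'
#' @param dose A `dose_plane` within the truth model's working range.
#' @param truth A [film_truth()].
#' @param pv_bg Background pixel value.
#' @param noise_frac Fractional PV noise SD (0.003 emulates scanner noise).
#' @param seed Seed for the noise stream.
#' @return A `film_scan`.
#' @export
simulate_film_response <- function(dose, truth = film_truth(), pv_bg = 40000,
                                   noise_frac = 0.003, seed = NULL) {
  stopifnot(inherits(dose, "dose_plane"))
  if (any(dose$values > truth$max_dose)) {
    stop_breathe4d(sprintf("dose exceeds the film model working range (%.3g Gy)",
                           truth$max_dose))
  }
  pv <- pv_bg * 10^(-truth_netod(truth, dose$values))
  if (noise_frac > 0) {
    pv <- pv * with_seed_if(seed, {
      matrix(1 + rnorm(length(pv), 0, noise_frac), nrow = nrow(pv))
    })
  }
  film_scan(pmin(pmax(pv, 1), 65535), dose$x, dose$y, pv_bg)
}

#' Generate calibration measurements
#'
#' Simulates one uniform calibration film patch per dose level and reads out
#' its mean net optical density — the synthetic counterpart of scanning the
#' calibration strips.
#'
#' @param levels Calibration dose levels in Gy.
#' @param truth A [film_truth()].
#' @param pv_bg Background pixel value.
#' @param noise_frac Fractional PV noise SD.
#' @param seed Seed.
#' @param patch_px Patch side length in pixels.
#' @return A tibble: `dose_gy`, `net_od`.
#' @export
make_calibration_data <- function(levels = c(0, 0.5, 1, 2, 3, 4, 5, 6, 8),
                                  truth = film_truth(), pv_bg = 40000,
                                  noise_frac = 0.003, seed = 1L,
                                  patch_px = 20L) {
  xy <- seq_len(patch_px)
  with_seed_if(seed, {
    ods <- vapply(levels, function(d) {
      dp <- dose_plane(matrix(d, patch_px, patch_px), xy, xy)
      scan <- simulate_film_response(dp, truth, pv_bg, noise_frac, seed = NULL)
      net_od(pv_bg, mean(scan$values))
    }, numeric(1))
    tibble(dose_gy = levels, net_od = ods)
  })
}

#' Fit the cubic netOD-to-dose calibration
#'
#' Least-squares third-order polynomial mapping netOD to dose, the standard
#' sensitometric calibration. The fitted curve must be monotone nondecreasing
#' over the fitted netOD range; a violation (e.g. non-monotone input data) is
#' an error.
#'
#' @param doses Dose levels in Gy (at least 5 distinct levels).
#' @param netods Measured netOD at each level.
#' @return A `calibration_curve`: coefficients (intercept first), fit range,
#'   and residuals.
#' @export
fit_calibration <- function(doses, netods) {
  stopifnot(length(doses) == length(netods))
  if (length(unique(doses)) <= 3L) {
    stop_breathe4d("cubic calibration needs more than 3 distinct dose levels (rank-deficient design)")
  }
  if (length(unique(doses)) < 5L) {
    stop_breathe4d("calibration requires at least 5 distinct dose levels spanning the working range")
  }
  fit <- lm(doses ~ netods + I(netods^2) + I(netods^3))
  cf <- unname(coef(fit))
  rng <- range(netods)
  grid <- seq(rng[1], rng[2], length.out = 201)
  deriv <- cf[2] + 2 * cf[3] * grid + 3 * cf[4] * grid^2
  if (any(deriv < 0)) {
    stop_breathe4d("fitted calibration is not monotone over the netOD range",
                   class = "breathe4d_calibration_monotone")
  }
  structure(list(coefficients = cf, range = rng,
                 residuals = tibble(dose_gy = doses, net_od = netods,
                                    residual_gy = unname(stats::residuals(fit)))),
            class = "calibration_curve")
}

predict_dose <- function(curve, netod) {
  cf <- curve$coefficients
  cf[1] + cf[2] * netod + cf[3] * netod^2 + cf[4] * netod^3
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> dose = %.3g + %.3g n + %.3g n^2 + %.3g n^3 (netOD in [%.3g, %.3g])\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4], x$range[1], x$range[2]))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble(term = c("(Intercept)", "netOD", "netOD^2", "netOD^3"),
         estimate = x$coefficients)
}

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble(n = nrow(x$residuals),
         sigma_gy = sd(x$residuals$residual_gy),
         max_abs_residual_gy = max(abs(x$residuals$residual_gy)),
         netod_min = x$range[1], netod_max = x$range[2])
}

#' Convert a film scan to dose
#'
#' Pixelwise netOD followed by the cubic calibration polynomial, clipped at
#' zero dose. netOD values outside the calibration range are clamped to the
#' range ends; the clamp count is recorded in the result's `n_clamped`
#' attribute, and saturated (above-range) pixels additionally warn. Slightly
#' negative netOD from scanner noise on unexposed film is clamped silently.
#'
#' @param scan A `film_scan`.
#' @param curve A `calibration_curve`.
#' @param pv_bg Background pixel value (default: the scan's).
#' @return A target-frame `dose_plane`.
#' @export
scan_to_dose <- function(scan, curve, pv_bg = NULL) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "calibration_curve"))
  pv_bg <- pv_bg %||% scan$pv_bg
  nod <- net_od(pv_bg, scan$values)
  n_low <- sum(nod < curve$range[1])
  n_high <- sum(nod > curve$range[2])
  n_clamped <- n_low + n_high
  if (n_high > 0) {
    warn(sprintf("%d pixel(s) above the calibration netOD range were clamped", n_high))
  }
  if (n_clamped > 0) nod <- pmin(pmax(nod, curve$range[1]), curve$range[2])
  out <- dose_plane(pmax(predict_dose(curve, nod), 0), scan$x, scan$y, "target")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Write / read a film scan as CSV
#'
#' Plain-text alternative to a single-channel 16-bit TIFF: a long-format CSV
#' of pixel values with the background value recorded in a header comment.
#'
#' @param scan A `film_scan`.
#' @param path File path.
#' @export
write_scan_csv <- function(scan, path) {
  con <- file(path, "w")
  writeLines(sprintf("# pv_bg=%g", scan$pv_bg), con)
  df <- expand.grid(x_mm = scan$x, y_mm = scan$y)
  df$pv <- as.vector(scan$values)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  pv_bg <- as.numeric(sub("# pv_bg=", "", hdr, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#")
  x <- sort(unique(df$x_mm)); y <- sort(unique(df$y_mm))
  vals <- matrix(df$pv[order(df$y_mm, df$x_mm)], nrow = length(x))
  film_scan(vals, x, y, pv_bg)
}


#' Write / read a calibration curve as JSON
#'
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(list(coefficients = curve$coefficients,
                            netod_range = curve$range,
                            residuals = curve$residuals),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = j$coefficients, range = j$netod_range,
                 residuals = tibble::as_tibble(j$residuals)),
            class = "calibration_curve")
}
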