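#' Gamma-index criteria
#'
#' Criteria of the 2D gamma comparison: dose tolerance as a percent of the
#' global normalization dose, distance-to-agreement (DTA) in mm, search
#' radius, sub-grid interpolation step, and a low-dose cutoff below which
#' reference points are excluded. Defaults follow the study: 3%/1 mm with
#' global normalization to the 6 Gy prescription and a 10% cutoff.
#'
#' @param dose_tol Dose tolerance in percent of `norm`.
#' @param dta Distance to agreement in mm.
#' @param norm Global normalization dose in Gy.
#' @param search_radius Search radius in mm (default `3 * dta`).
#' @param step Interpolation step in mm (must be `<= dta / 5`).
#' @param cutoff Low-dose cutoff in percent of `norm`.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 3, dta = 1, norm = 6,
                           search_radius = NULL, step = 0.1, cutoff = 10) {
  assert_scalar_num(dose_tol, "dose_tol", positive = TRUE)
  assert_scalar_num(dta, "dta", positive = TRUE)
  assert_scalar_num(norm, "norm", positive = TRUE)
  search_radius <- search_radius %||% (3 * dta)
  assert_scalar_num(search_radius, "search_radius", positive = TRUE)
  assert_scalar_num(step, "step", positive = TRUE)
  if (step > dta / 5 + 1e-12) stop_breathe4d("`step` must be at most dta / 5")
  assert_scalar_num(cutoff, "cutoff", nonneg = TRUE)
  structure(list(dose_tol = dose_tol, dta = dta, norm = norm,
                 search_radius = search_radius, step = step, cutoff = cutoff),
            class = "gamma_criteria")
}

#' Gamma ROI from a target mask
#'
#' Film-plane projection of the GTV dilated by a uniform 2D margin: the
#' region over which passing rates are scored.
#'
#' @param mask A `structure_mask` (the GTV).
#' @param x,y Dose grid coordinates in mm.
#' @param dilation Margin in mm (default 2).
#' @return Logical matrix on the dose grid.
#' @export
target_roi <- function(mask, x, y, dilation = 2) {
  proj <- mask_projection(mask, x, y)
  if (dilation <= 0) return(proj)
  gs <- if (length(x) > 1) x[2] - x[1] else 1
  nmax <- floor(dilation / gs)
  out <- proj
  d <- dim(proj)
  for (di in -nmax:nmax) for (dj in -nmax:nmax) {
    if ((di^2 + dj^2) * gs^2 > dilation^2 || (di == 0 && dj == 0)) next
    sx <- max(1, 1 - di):min(d[1], d[1] - di)
    sy <- max(1, 1 - dj):min(d[2], d[2] - dj)
    out[sx + di, sy + dj] <- out[sx + di, sy + dj] | proj[sx, sy]
  }
  out
}

# bilinear upsample of matrix V (grid x0/gs) onto target coordinates xs, ys
.bilinear <- function(V, x, y, xs, ys) {
  gs_x <- x[2] - x[1]; gs_y <- y[2] - y[1]
  tx <- (xs - x[1]) / gs_x
  ty <- (ys - y[1]) / gs_y
  fi <- pmin(pmax(floor(tx) + 1L, 1L), length(x) - 1L)
  fj <- pmin(pmax(floor(ty) + 1L, 1L), length(y) - 1L)
  ax <- pmin(pmax(tx - (fi - 1L), 0), 1)
  ay <- pmin(pmax(ty - (fj - 1L), 0), 1)
  V[fi, fj] * ((1 - ax) %o% (1 - ay)) +
    V[fi + 1L, fj] * (ax %o% (1 - ay)) +
    V[fi, fj + 1L] * ((1 - ax) %o% ay) +
    V[fi + 1L, fj + 1L] * (ax %o% ay)
}

#' 2D gamma comparison of two dose planes
#'
#' For each reference point inside the ROI (and above the low-dose cutoff),
#' the gamma index is the minimum over a search disc of
#' `sqrt((d / dta)^2 + (dD / (tol * norm))^2)`, where `d` is the spatial
#' offset, and `dD` the difference between the sub-grid-interpolated
#' evaluated dose at the offset position and the reference dose at the point
#' (reference-to-evaluated direction). A point passes when gamma <= 1.
#'
#' @param reference,evaluated `dose_plane`s on the same grid.
#' @param criteria A [gamma_criteria()].
#' @param roi Logical matrix on the dose grid; must be nonempty.
#' @return A `gamma_map`: per-point gamma values (NA outside the scored
#'   region), the scored ROI, criteria and passing rate.
#' @export
gamma_2d <- function(reference, evaluated, criteria = gamma_criteria(), roi) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"))
  if (length(reference$x) != length(evaluated$x) ||
      max(abs(reference$x - evaluated$x)) > 1e-6 ||
      max(abs(reference$y - evaluated$y)) > 1e-6) {
    stop_breathe4d("reference and evaluated planes must share the grid")
  }
  if (missing(roi) || !any(roi)) stop_breathe4d("ROI is empty")
  x <- reference$x; y <- reference$y
  scored <- roi & reference$values >= criteria$cutoff / 100 * criteria$norm
  if (!any(scored)) stop_breathe4d("no ROI points above the dose cutoff")
  pts <- which(scored, arr.ind = TRUE)
  R <- criteria$search_radius
  # snap the interpolation step to an exact divisor of the grid spacing so
  # that every reference point lies on the upsampled lattice
  gs <- x[2] - x[1]
  st <- gs / ceiling(gs / criteria$step - 1e-9)
  lat <- function(coord, idx) {
    i_lo <- max(0, floor((min(coord[idx]) - R - coord[1]) / st))
    i_hi <- min(round((coord[length(coord)] - coord[1]) / st),
                ceiling((max(coord[idx]) + R - coord[1]) / st))
    coord[1] + st * (i_lo:i_hi)
  }
  xs <- lat(x, pts[, 1]); ys <- lat(y, pts[, 2])
  E <- .bilinear(evaluated$values, x, y, xs, ys)
  ui <- as.integer(round((x[pts[, 1]] - xs[1]) / st)) + 1L
  uj <- as.integer(round((y[pts[, 2]] - ys[1]) / st)) + 1L
  Dr <- reference$values[pts]
  delta <- criteria$dose_tol / 100 * criteria$norm

  nmax <- floor(R / st)
  og <- expand.grid(oi = -nmax:nmax, oj = -nmax:nmax)
  d2 <- (og$oi^2 + og$oj^2) * st^2
  og <- og[d2 <= R^2, ]
  d2 <- d2[d2 <= R^2]
  ord <- order(d2)
  og <- og[ord, ]; d2 <- d2[ord]
  dist_term <- d2 / criteria$dta^2

  g2 <- rep(Inf, nrow(pts))
  nxs <- length(xs); nys <- length(ys)
  for (k in seq_len(nrow(og))) {
    if (dist_term[k] >= max(g2)) break
    ii <- ui + og$oi[k]; jj <- uj + og$oj[k]
    ok <- ii >= 1L & ii <= nxs & jj >= 1L & jj <= nys
    if (!any(ok)) next
    dd <- (E[cbind(ii[ok], jj[ok])] - Dr[ok]) / delta
    g2[ok] <- pmin(g2[ok], dist_term[k] + dd^2)
  }
  gam <- matrix(NA_real_, length(x), length(y))
  gam[pts] <- sqrt(g2)
  structure(list(gamma = gam, roi = scored, x = x, y = y, criteria = criteria,
                 passing_rate = 100 * mean(g2 <= 1)),
            class = "gamma_map")
}

#' Passing rate of a gamma map
#'
#' Percent of scored ROI points with gamma <= 1.
#'
#' @param map A `gamma_map`.
#' @return Passing rate in percent.
#' @export
passing_rate <- function(map) {
  stopifnot(inherits(map, "gamma_map"))
  g <- map$gamma[map$roi]
  if (!length(g)) stop_breathe4d("gamma map has no scored points")
  100 * mean(g <= 1)
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf("<gamma_map> %d ROI points, %g%%/%g mm: passing rate %.1f%%\n",
              sum(x$roi), x$criteria$dose_tol, x$criteria$dta, x$passing_rate))
  invisible(x)
}

#' @export
tidy.gamma_map <- function(x, ...) {
  pts <- which(x$roi, arr.ind = TRUE)
  tibble(x_mm = x$x[pts[, 1]], y_mm = x$y[pts[, 2]],
         gamma = x$gamma[pts], pass = x$gamma[pts] <= 1)
}

#' @export
glance.gamma_map <- function(x, ...) {
  g <- x$gamma[x$roi]
  tibble(n_points = length(g), passing_rate = x$passing_rate,
         gamma_mean = mean(g), gamma_max = max(g),
         dose_tol = x$criteria$dose_tol, dta = x$criteria$dta,
         norm = x$criteria$norm)
}

#' Plot a gamma map
#' @param object A `gamma_map`.
#' @param ... Ignored.
#' @return A ggplot raster of gamma values over the ROI.
#' @export
autoplot.gamma_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_mm, y = .data$y_mm, fill = .data$gamma)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(gamma), limits = c(0, NA)) +
    coord_equal() +
    labs(x = "X (mm)", y = "Y (mm)",
         title = sprintf("gamma %g%%/%g mm: %.1f%% passing",
                         object$criteria$dose_tol, object$criteria$dta,
                         object$passing_rate)) +
    theme_minimal()
}

#' Paired comparison of passing-rate groups
#'
#' Standard paired t-test between two matched lists of passing rates, with
#' significance at 0.05. Zero variance of the differences is reported as
#' degenerate (no p-value) rather than an error.
#'
#' @param rates_a,rates_b Equal-length numeric vectors (length >= 2).
#' @return A one-row tibble: `mean_diff`, `t`, `p`, `significant`,
#'   `degenerate`, `n`.
#' @export
paired_comparison <- function(rates_a, rates_b) {
  if (length(rates_a) != length(rates_b) || length(rates_a) < 2L) {
    stop_breathe4d("paired comparison needs two equal-length vectors of length >= 2")
  }
  d <- rates_a - rates_b
  if (sd(d) < 1e-12) {
    return(tibble(mean_diff = mean(d), t = NA_real_, p = NA_real_,
                  significant = NA, degenerate = TRUE, n = length(d)))
  }
  tt <- t.test(rates_a, rates_b, paired = TRUE)
  tibble(mean_diff = mean(d), t = unname(tt$statistic), p = tt$p.value,
         significant = tt$p.value <= 0.05, degenerate = FALSE, n = length(d))
}
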