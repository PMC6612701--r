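# independent brute-force gamma: per-point search over all interpolated
# offsets, structured differently from the package's offset-sweep engine
oracle_gamma <- function(ref, ev, crit, roi) {
  x <- ref$x; y <- ref$y
  R <- crit$search_radius
  st <- (x[2] - x[1]) / ceiling((x[2] - x[1]) / crit$step - 1e-9)
  delta <- crit$dose_tol / 100 * crit$norm
  interp <- function(px, py) {
    tx <- (px - x[1]) / (x[2] - x[1]); ty <- (py - y[1]) / (y[2] - y[1])
    fi <- pmin(pmax(floor(tx) + 1, 1), length(x) - 1)
    fj <- pmin(pmax(floor(ty) + 1, 1), length(y) - 1)
    ax <- pmin(pmax(tx - (fi - 1), 0), 1); ay <- pmin(pmax(ty - (fj - 1), 0), 1)
    ev$values[cbind(fi, fj)] * (1 - ax) * (1 - ay) +
      ev$values[cbind(fi + 1, fj)] * ax * (1 - ay) +
      ev$values[cbind(fi, fj + 1)] * (1 - ax) * ay +
      ev$values[cbind(fi + 1, fj + 1)] * ax * ay
  }
  offs <- expand.grid(ox = seq(-R, R, by = st), oy = seq(-R, R, by = st))
  offs <- offs[offs$ox^2 + offs$oy^2 <= R^2 + 1e-12, ]
  pts <- which(roi & ref$values >= crit$cutoff / 100 * crit$norm, arr.ind = TRUE)
  gam <- matrix(NA_real_, length(x), length(y))
  for (i in seq_len(nrow(pts))) {
    x0 <- x[pts[i, 1]]; y0 <- y[pts[i, 2]]
    px <- x0 + offs$ox
    py <- y0 + offs$oy
    ok <- px >= x[1] & px <= x[length(x)] & py >= y[1] & py <= y[length(y)]
    dd <- (interp(px[ok], py[ok]) - ref$values[pts[i, 1], pts[i, 2]]) / delta
    d2 <- ((px[ok] - x0)^2 + (py[ok] - y0)^2) / crit$dta^2
    gam[pts[i, 1], pts[i, 2]] <- sqrt(min(d2 + dd^2))
  }
  gam
}

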