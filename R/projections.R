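#' Intensity projections over phase volumes
#'
#' Builds the maximum intensity projection (MIP, voxelwise maximum) or
#' average intensity projection (AIP, voxelwise arithmetic mean) over a
#' subset of phase volumes. Gated projections use the gated phase subset;
#' the default uses every phase.
#'
#' @param pvs A `phase_volume_set`.
#' @param kind `"MIP"` or `"AIP"`.
#' @param phases Phase labels (bin centers, %) to include; default all.
#' @return A `projection_volume` (a `voxel_grid` with `kind` and `phases`
#'   attributes).
#' @export
project <- function(pvs, kind = c("MIP", "AIP"), phases = NULL) {
  stopifnot(inherits(pvs, "phase_volume_set"))
  kind <- match.arg(kind)
  phases <- phases %||% pvs$phases
  missing <- setdiff(phases, pvs$phases)
  if (length(missing)) {
    stop_breathe4d(sprintf("unknown phase label(s) %s; available: %s",
                           paste(missing, collapse = ", "),
                           paste(pvs$phases, collapse = ", ")))
  }
  if (!length(phases)) stop_breathe4d("`phases` must be nonempty")
  idx <- match(phases, pvs$phases)
  vals <- lapply(pvs$volumes[idx], function(v) v$values)
  out <- if (kind == "MIP") Reduce(pmax, vals) else Reduce(`+`, vals) / length(vals)
  vol <- pvs$volumes[[idx[1]]]
  vol$values <- out
  attr(vol, "kind") <- kind
  attr(vol, "phases") <- phases
  class(vol) <- c("projection_volume", class(vol))
  vol
}

#' HU line profile through a volume
#'
#' Nearest-voxel line profile along the X (lateral) or Y (longitudinal) axis
#' through a given point, as used to inspect how target HU is smeared along
#' the motion axis in AIP images while MIP stays flat across the swept region.
#'
#' @param vol A `voxel_grid`.
#' @param axis `"x"` or `"y"`.
#' @param through Length-3 physical point (mm) the line passes through.
#' @return A tibble: `position_mm`, `hu`.
#' @export
hu_profile <- function(vol, axis = c("y", "x"), through = c(0, 0, 0)) {
  stopifnot(inherits(vol, "voxel_grid"))
  axis <- match.arg(axis)
  ax_i <- if (axis == "x") 1L else 2L
  idx <- vapply(1:3, function(i) {
    ci <- grid_axis(vol, i)
    if (through[i] < min(ci) - vol$spacing / 2 || through[i] > max(ci) + vol$spacing / 2) {
      stop_breathe4d("`through` point lies outside the grid")
    }
    which.min(abs(ci - through[i]))
  }, integer(1))
  pos <- grid_axis(vol, ax_i)
  hu <- switch(axis,
               x = vol$values[, idx[2], idx[3]],
               y = vol$values[idx[1], , idx[3]])
  tibble(position_mm = pos, hu = as.numeric(hu))
}

#' Export an HU profile as CSV
#'
#' @param profile A tibble from [hu_profile()].
#' @param path Output path.
#' @export
write_profile_csv <- function(profile, path) {
  readr::write_csv(profile, path)
  invisible(path)
}
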