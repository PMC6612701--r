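#' Structure masks and target geometry
#'
#' Binary voxel masks (GTV/ITV/PTV) share the geometry of their source
#' volume. Volume is the plain voxel count times voxel volume; partial-volume
#' accuracy comes from the supersampled rendering upstream, not from any mesh
#' correction.
#'
#' @name structure_mask
NULL

new_structure_mask <- function(values, spacing, origin, label = "GTV") {
  structure(list(values = values, spacing = spacing, origin = origin, label = label),
            class = c("structure_mask", "voxel_grid"))
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels, %.3f cm^3\n",
              x$label, sum(x$values), mask_volume_cm3(x)))
  invisible(x)
}

# flood-fill away everything reachable from the volume border through the
# candidate set (iterative 6-neighbour dilation; the body block is solid)
.drop_border_components <- function(cand) {
  d <- dim(cand)
  vis <- array(FALSE, dim = d)
  vis[c(1, d[1]), , ] <- cand[c(1, d[1]), , ]
  vis[, c(1, d[2]), ] <- vis[, c(1, d[2]), ] | cand[, c(1, d[2]), ]
  vis[, , c(1, d[3])] <- vis[, , c(1, d[3])] | cand[, , c(1, d[3])]
  repeat {
    grown <- vis
    grown[-1, , ] <- grown[-1, , ] | vis[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | vis[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | vis[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | vis[, -1, ]
    grown[, , -1] <- grown[, , -1] | vis[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | vis[, , -1]
    grown <- grown & cand
    if (identical(grown, vis)) break
    vis <- grown
  }
  cand & !vis
}

# 26-connected components over a candidate logical array; returns the largest
# component restricted to linear indices `seeds_from` (logical array)
.largest_component <- function(cand) {
  d <- dim(cand)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  best <- NULL
  repeat {
    remaining <- which(cand & !visited)
    if (!length(remaining)) break
    comp <- logical(length(cand)); dim(comp) <- d
    frontier <- remaining[1L]
    comp[frontier] <- TRUE
    visited[frontier] <- TRUE
    while (length(frontier)) {
      fi <- arrayInd(frontier, d)
      nb_list <- lapply(seq_len(nrow(offs)), function(o) {
        ni <- fi
        ni[, 1] <- ni[, 1] + offs[o, 1]
        ni[, 2] <- ni[, 2] + offs[o, 2]
        ni[, 3] <- ni[, 3] + offs[o, 3]
        ok <- ni[, 1] >= 1 & ni[, 1] <= d[1] &
              ni[, 2] >= 1 & ni[, 2] <= d[2] &
              ni[, 3] >= 1 & ni[, 3] <= d[3]
        ni <- ni[ok, , drop = FALSE]
        (ni[, 3] - 1L) * d[1] * d[2] + (ni[, 2] - 1L) * d[1] + ni[, 1]
      })
      nb <- unique(unlist(nb_list))
      nb <- nb[cand[nb] & !visited[nb]]
      visited[nb] <- TRUE
      comp[nb] <- TRUE
      frontier <- nb
    }
    if (is.null(best) || sum(comp) > sum(best)) best <- comp
  }
  best
}

#' Auto-contour the target on a CT volume
#'
#' Thresholds the volume (inclusive, half-max style) and keeps the largest
#' 26-connected component that
#' does not belong to the body: the body block (0 HU) also exceeds the
#' default threshold, but it always touches the volume border, so
#' border-touching components are discarded. When the volume carries phantom
#' provenance the search is restricted to the insert interior directly, which
#' is equivalent and much faster.
#'
#' The default threshold is the midpoint of insert and target HU (-375 HU
#' with the default materials): a half-occupancy edge criterion that replaces
#' the study's manual contour adjustment with a reproducible rule.
#'
#' @param vol A `voxel_grid`.
#' @param threshold Threshold in HU; must lie between insert and target HU.
#' @return A `structure_mask` labelled `"GTV"`.
#' @export
segment_target <- function(vol, threshold = NULL) {
  stopifnot(inherits(vol, "voxel_grid"))
  spec <- attr(vol, "phantom_spec")
  if (is.null(threshold)) {
    if (is.null(spec)) stop_breathe4d("`threshold` required for volumes without phantom provenance")
    threshold <- (spec$insert_HU + spec$target_HU) / 2
  }
  cand <- vol$values >= threshold
  if (!is.null(spec)) {
    if (threshold <= spec$insert_HU || threshold >= spec$target_HU) {
      stop_breathe4d(sprintf("threshold %.0f HU must lie between insert (%.0f) and target (%.0f) HU",
                             threshold, spec$insert_HU, spec$target_HU),
                     class = "breathe4d_empty_segmentation")
    }
    inside <- lapply(1:3, function(i) {
      abs(grid_axis(vol, i)) < spec$insert_extent[i] / 2 - vol$spacing / 2
    })
    cand <- cand & outer(outer(inside[[1]], inside[[2]], "&"), inside[[3]], "&")
  } else {
    cand <- .drop_border_components(cand)
  }
  if (!any(cand)) {
    stop_breathe4d("segmentation is empty at this threshold",
                   class = "breathe4d_empty_segmentation")
  }
  comp <- .largest_component(cand)
  new_structure_mask(comp, vol$spacing, vol$origin, "GTV")
}

#' Internal target volume from a phase range
#'
#' Union of the per-phase target masks whose bin centers lie in
#' `[phase_range[1], phase_range[2]]` (inclusive). The gated window is
#' `c(30, 70)` (end-exhalation); the nongated ITV uses all phases
#' (`c(0, 100)`).
#'
#' @param pvs A `phase_volume_set`.
#' @param phase_range Length-2 numeric phase window in percent.
#' @param threshold Segmentation threshold passed to [segment_target()].
#' @return A `structure_mask` labelled `"ITV"`.
#' @export
itv_from_phases <- function(pvs, phase_range = c(0, 100), threshold = NULL) {
  stopifnot(inherits(pvs, "phase_volume_set"), length(phase_range) == 2L)
  sel <- pvs$phases >= phase_range[1] & pvs$phases <= phase_range[2]
  if (!any(sel)) {
    stop_breathe4d(sprintf("no phases in [%g, %g]; available: %s",
                           phase_range[1], phase_range[2],
                           paste(pvs$phases, collapse = ", ")))
  }
  masks <- lapply(pvs$volumes[sel], segment_target, threshold = threshold)
  vals <- Reduce(`|`, lapply(masks, function(m) m$values))
  out <- masks[[1]]
  out$values <- vals
  out$label <- "ITV"
  out
}

#' Theoretical internal target volume of a translated sphere
#'
#' The continuous envelope of a sphere of radius `r` translated over a
#' longitudinal range `L` is a sphere plus a cylinder:
#' `ITV_th = 4/3 * pi * r^3 + L * pi * r^2`, returned in cm^3.
#'
#' @param r Sphere radius in mm.
#' @param L Peak-to-trough motion range in mm.
#' @return Volume in cm^3.
#' @export
#' @examples
#' itv_theoretical(10, 0)   # 4.19 cm^3 sphere limit
#' itv_theoretical(10, 30)  # 13.61 cm^3
itv_theoretical <- function(r, L) {
  assert_scalar_num(r, "r", positive = TRUE)
  assert_scalar_num(L, "L", nonneg = TRUE)
  (4 / 3 * pi * r^3 + L * pi * r^2) / 1000
}

#' Expand a mask by a uniform margin
#'
#' Euclidean (isotropic) dilation by `margin` mm, used to grow the GTV/ITV
#' into the PTV (default clinical margin in this study: 5 mm).
#'
#' @param mask A `structure_mask`.
#' @param margin Margin in mm (>= 0).
#' @param label Label of the result (default `"PTV"`).
#' @return A `structure_mask` containing the input.
#' @export
expand_margin <- function(mask, margin = 5, label = "PTV") {
  stopifnot(inherits(mask, "structure_mask"))
  assert_scalar_num(margin, "margin", nonneg = TRUE)
  if (margin == 0) { mask$label <- label; return(mask) }
  d <- dim(mask$values)
  nmax <- floor(margin / mask$spacing)
  out <- array(FALSE, dim = d)
  for (di in -nmax:nmax) for (dj in -nmax:nmax) for (dk in -nmax:nmax) {
    if ((di^2 + dj^2 + dk^2) * mask$spacing^2 > margin^2) next
    sx <- max(1, 1 - di):min(d[1], d[1] - di)
    sy <- max(1, 1 - dj):min(d[2], d[2] - dj)
    sz <- max(1, 1 - dk):min(d[3], d[3] - dk)
    out[sx + di, sy + dj, sz + dk] <- out[sx + di, sy + dj, sz + dk] |
      mask$values[sx, sy, sz]
  }
  new_structure_mask(out, mask$spacing, mask$origin, label)
}

#' Mask volume in cm^3
#' @param mask A `structure_mask`.
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$values) * mask$spacing^3 / 1000
}

#' Mask centroid in mm
#' @param mask A `structure_mask`.
#' @return Length-3 physical centroid (X, Y, Z).
#' @export
mask_centroid <- function(mask) {
  idx <- arrayInd(which(mask$values), dim(mask$values))
  mask$origin + (colMeans(idx) - 1) * mask$spacing
}

#' Percent volume variation against a reference
#'
#' `(test / ref - 1) * 100`, the statistic used for GTV-vs-true-volume and
#' AIP-vs-MIP ITV comparisons.
#'
#' @param test_volume,ref_volume Volumes in cm^3; `ref_volume > 0`.
#' @return Percent variation.
#' @export
#' @examples
#' variation(8.36, 9.06)  # -7.73 %
variation <- function(test_volume, ref_volume) {
  if (any(ref_volume <= 0)) stop_breathe4d("`ref_volume` must be > 0")
  (test_volume / ref_volume - 1) * 100
}
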