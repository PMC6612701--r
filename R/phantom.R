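#' Digital thorax phantom specification
#'
#' A voxelizable stand-in for a dynamic thorax phantom: a soft-tissue sphere
#' (the target, default 20 mm diameter) embedded in a very low density
#' foam-like insert, itself inside a water-equivalent body block. The target
#' translates longitudinally (Y, cranio-caudal) inside the insert; the film
#' plane is the coronal plane through the target.
#'
#' Default Hounsfield values (target +40, insert -790, body 0) put the
#' half-occupancy segmentation threshold at -375 HU.
#'
#' @param target_radius Target sphere radius in mm.
#' @param target_HU,insert_HU,body_HU Hounsfield units of the three materials;
#'   `target_HU` must exceed `insert_HU`.
#' @param insert_extent,body_extent Full box extents (mm) along (X, Y, Z); the
#'   voxel grid covers `body_extent`, centered on the phantom.
#' @param film_plane_z Coronal film plane offset (mm, Z).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(target_radius = 10,
                         target_HU = 40, insert_HU = -790, body_HU = 0,
                         insert_extent = c(40, 70, 40),
                         body_extent = c(60, 90, 60),
                         film_plane_z = 0) {
  assert_scalar_num(target_radius, "target_radius", positive = TRUE)
  if (target_HU <= insert_HU) stop_breathe4d("`target_HU` must exceed `insert_HU`")
  stopifnot(length(insert_extent) == 3L, length(body_extent) == 3L)
  if (any(insert_extent > body_extent)) stop_breathe4d("insert must fit inside body")
  if (any(insert_extent / 2 < target_radius)) {
    stop_breathe4d("target sphere does not fit inside the insert")
  }
  structure(list(
    target_radius = target_radius, target_HU = target_HU,
    insert_HU = insert_HU, body_HU = body_HU,
    insert_extent = insert_extent, body_extent = body_extent,
    film_plane_z = film_plane_z
  ), class = "phantom_spec")
}

#' Voxel grid container
#'
#' A dense 3D image: HU values on an isotropic grid with axes ordered
#' (X lateral, Y longitudinal/cranio-caudal, Z anterior-posterior). `origin`
#' is the physical coordinate (mm) of the center of voxel `[1, 1, 1]`.
#'
#' @param values 3D numeric array.
#' @param spacing Isotropic voxel spacing in mm.
#' @param origin Length-3 physical coordinate of the first voxel center.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing = 1, origin = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  assert_scalar_num(spacing, "spacing", positive = TRUE)
  origin <- origin %||% (-(dim(values) - 1) / 2 * spacing)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

# physical coordinates of voxel centers along axis i
grid_axis <- function(vol, i) {
  vol$origin[i] + (seq_len(dim(vol$values)[i]) - 1L) * vol$spacing
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

# body + insert background (no target, no noise) on the phantom grid
.phantom_base <- function(spec, spacing = 1) {
  half <- spec$body_extent / 2
  ax <- lapply(1:3, function(i) seq(-half[i], half[i], by = spacing))
  dims <- vapply(ax, length, integer(1))
  vals <- array(spec$body_HU, dim = dims)
  ins <- lapply(1:3, function(i) which(abs(ax[[i]]) <= spec$insert_extent[i] / 2))
  vals[ins[[1]], ins[[2]], ins[[3]]] <- spec$insert_HU
  vol <- voxel_grid(vals, spacing, origin = c(-half[1], -half[2], -half[3]))
  attr(vol, "phantom_spec") <- spec
  vol
}

# add the supersampled target sphere (center on the Y axis at `displacement`)
# into `vol`, optionally restricted to Y indices [y_lo, y_hi]
.add_sphere <- function(vol, spec, displacement, supersample = 3L,
                        y_lo = 1L, y_hi = dim(vol$values)[2]) {
  r <- spec$target_radius
  cx <- grid_axis(vol, 1); cy <- grid_axis(vol, 2); cz <- grid_axis(vol, 3)
  pad <- r + vol$spacing
  ix <- which(abs(cx) <= pad)
  iy <- which(cy >= displacement - pad & cy <= displacement + pad)
  iy <- iy[iy >= y_lo & iy <= y_hi]
  iz <- which(abs(cz) <= pad)
  if (!length(ix) || !length(iy) || !length(iz)) return(vol)
  s <- as.integer(supersample)
  off <- ((seq_len(s) - (s + 1) / 2) / s) * vol$spacing
  occ <- array(0, dim = c(length(ix), length(iy), length(iz)))
  for (ox in off) {
    dx2 <- (cx[ix] + ox)^2
    for (oy in off) {
      dy2 <- (cy[iy] + oy - displacement)^2
      dxy <- outer(dx2, dy2, "+")
      for (oz in off) {
        dz2 <- (cz[iz] + oz)^2
        occ <- occ + (outer(dxy, dz2, "+") <= r^2)
      }
    }
  }
  occ <- occ / s^3
  block <- vol$values[ix, iy, iz, drop = FALSE]
  vol$values[ix, iy, iz] <- block + occ * (spec$target_HU - spec$insert_HU)
  vol
}

#' Render the phantom at a target displacement
#'
#' Rasterizes the phantom onto an isotropic voxel grid. Partial-volume
#' fractions at the sphere edge are computed by `supersample`^3 subvoxel
#' sampling; optional additive Gaussian HU noise emulates imaging noise.
#'
#' @param spec A [phantom_spec()].
#' @param displacement Longitudinal target center position in mm.
#' @param spacing Voxel size in mm (default 1.0, slice-thickness-like).
#' @param noise_sd Additive HU noise SD (0 = noiseless).
#' @param seed Seed used when `noise_sd > 0`.
#' @param supersample Subvoxel sampling factor per axis.
#' @return A `voxel_grid` carrying the `phantom_spec` as an attribute.
#' @export
render_phantom <- function(spec, displacement = 0, spacing = 1,
                           noise_sd = 0, seed = NULL, supersample = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (abs(displacement) + spec$target_radius > spec$insert_extent[2] / 2) {
    stop_breathe4d(sprintf(
      "target (radius %.3g mm) at displacement %.3g mm leaves the insert (Y half-extent %.3g mm)",
      spec$target_radius, displacement, spec$insert_extent[2] / 2),
      class = "breathe4d_geometry")
  }
  vol <- .phantom_base(spec, spacing)
  vol <- .add_sphere(vol, spec, displacement, supersample)
  if (noise_sd > 0) {
    vol$values <- vol$values + with_seed_if(seed, {
      array(rnorm(length(vol$values), 0, noise_sd), dim = dim(vol$values))
    })
  }
  vol
}

#' Write / read a volume as NIfTI-1
#'
#' @param vol A `voxel_grid` (or `structure_mask`).
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `voxel_grid`.
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  if (is.logical(vals)) vals <- vals * 1  # masks stored as 0/1
  img <- RNifti::asNifti(vals, pixdim = rep(vol$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_grid(array(as.numeric(img), dim = dim(img)),
             spacing = RNifti::pixdim(img)[1])
}
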