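#' Scalar 3D image on a regular grid
#'
#' A `volume3d` is a numeric 3D array carrying voxel spacing and the world
#' coordinate of the center of voxel `[1,1,1]` (the origin). The isocenter is
#' the world origin. Voxels outside the reconstruction field of view are
#' marked with the null value `NA`; they contribute zero to forward
#' projections and are excluded from similarity and metric sums.
#'
#' @param data numeric 3D array.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param origin world coordinate (mm) of the first voxel center; default
#'   centers the grid on the isocenter.
#' @return An object of class `volume3d` (a 3D array with attributes).
#' @export
volume3d <- function(data, spacing, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (is.null(origin)) origin <- -(dim(data) - 1) * spacing / 2
  structure(data, spacing = spacing, origin = as.numeric(origin),
            class = c("volume3d", "array"))
}

#' Grid metadata for a 3D volume
#'
#' @param shape integer grid dimensions (length 1 or 3).
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param origin world coordinate of the first voxel center; default centered.
#' @return A list of class `grid3d` with fields `shape`, `spacing`, `origin`.
#' @export
grid3d <- function(shape, spacing, origin = NULL) {
  shape <- rep(as.integer(shape), length.out = 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d: %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Extract the grid metadata of a volume
#' @param vol a `volume3d` (or a `grid3d`, returned unchanged).
#' @return a `grid3d`.
#' @export
vol_grid <- function(vol) {
  if (inherits(vol, "grid3d")) return(vol)
  grid3d(dim(vol), attr(vol, "spacing"), attr(vol, "origin"))
}

#' @export
print.volume3d <- function(x, ...) {
  g <- vol_grid(x)
  rng <- range(x, na.rm = TRUE)
  cat(sprintf("volume3d: %s voxels @ %s mm; range [%.4g, %.4g]; %d null voxels\n",
              paste(g$shape, collapse = "x"),
              paste(signif(g$spacing, 4), collapse = "x"),
              rng[1], rng[2], sum(is.na(x))))
  invisible(x)
}

# world coordinates of voxel centers along one axis
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Field-of-view cylinder mask
#'
#' Logical mask of voxels inside the reconstruction FOV: the cylinder about
#' the rotation (z) axis of radius `fov_radius`.
#'
#' @param grid a `grid3d` or `volume3d`.
#' @param fov_radius cylinder radius in mm; default the largest cylinder
#'   inscribed in the grid's x-y extent.
#' @return logical 3D array.
#' @export
fov_mask <- function(grid, fov_radius = NULL) {
  grid <- vol_grid(grid)
  if (is.null(fov_radius)) fov_radius <- default_fov_radius(grid)
  x <- axis_coords(grid, 1); y <- axis_coords(grid, 2)
  r2 <- outer(x^2, y^2, "+")
  array(rep(r2 <= fov_radius^2, grid$shape[3]), grid$shape)
}

default_fov_radius <- function(grid) {
  grid <- vol_grid(grid)
  min((grid$shape[1] - 1) * grid$spacing[1], (grid$shape[2] - 1) * grid$spacing[2]) / 2
}

#' Apply the null-FOV convention to a volume
#'
#' Sets voxels outside the FOV cylinder to the null value (`NA`).
#'
#' @inheritParams fov_mask
#' @param vol a `volume3d`.
#' @return the volume with out-of-FOV voxels set to `NA`.
#' @export
apply_fov_null <- function(vol, fov_radius = NULL) {
  m <- fov_mask(vol, fov_radius)
  vol[!m] <- NA_real_
  vol
}

# grid at a coarser level: shape reduced by `factor`, spacing increased,
# grid kept centered on the same world extent
level_grid <- function(grid, factor) {
  grid <- vol_grid(grid)
  stopifnot(all(grid$shape %% factor == 0))
  grid3d(grid$shape %/% factor, grid$spacing * factor)
}

# block-average pooling of a 3D array by an integer factor (volumes) --------
block_mean3 <- function(a, factor) {
  if (factor == 1) return(a)
  d <- dim(a)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  dim(a) <- c(factor, dn[1], factor, dn[2], factor, dn[3])
  out <- apply(a, c(2, 4, 6), mean)
  array(out, dn)
}

# block-average pooling of a 2D matrix
block_mean2 <- function(m, factor) {
  if (factor == 1) return(m)
  d <- dim(m)
  stopifnot(all(d %% factor == 0))
  dn <- d %/% factor
  dim(m) <- c(factor, dn[1], factor, dn[2])
  matrix(apply(m, c(2, 4), mean), dn[1], dn[2])
}

#' Ordered stack of 2D projection images
#'
#' Line-integral (log-converted) projection images with their acquisition
#' geometry. Frame `t` of `data[, , t]` was acquired at `geometry$angles[t]`
#' degrees and `geometry$times[t]` seconds; image axes are the detector u
#' (in-plane) and v (axial) directions.
#'
#' @param data numeric array `(nu, nv, n_proj)` of line integrals.
#' @param geometry a `scan_geometry`.
#' @return An object of class `projection_stack`.
#' @export
projection_stack <- function(data, geometry) {
  validate_geometry(geometry)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[3] != n_frames(geometry))
    stop("projection stack has ", dim(data)[3], " frames but geometry describes ",
         n_frames(geometry))
  if (dim(data)[1] != geometry$nu || dim(data)[2] != geometry$nv)
    stop("projection image shape does not match detector description")
  structure(list(data = data, geometry = geometry), class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("projection_stack: %d frames of %d x %d px, values [%.3g, %.3g]\n",
              n_frames(x), dim(x$data)[1], dim(x$data)[2],
              min(x$data), max(x$data)))
  print(x$geometry)
  invisible(x)
}

# projections and geometry at a coarser resolution level
level_projections <- function(projs, factor) {
  if (factor == 1) return(projs)
  g <- level_geometry(projs$geometry, factor)
  d <- dim(projs$data)
  arr <- array(0, c(g$nu, g$nv, d[3]))
  for (t in seq_len(d[3])) arr[, , t] <- block_mean2(projs$data[, , t], factor)
  projection_stack(arr, g)
}
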