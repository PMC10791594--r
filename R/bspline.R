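#' Cubic B-spline control point grid
#'
#' A free-form deformation is parameterised by 3-vector displacements (mm) on
#' a coarse regular grid of control points in world coordinates. The grid
#' covers the image domain plus one B-spline support margin on every side, so
#' the tensor-product basis has full support at every image voxel.
#'
#' @param grid image grid to cover (`grid3d` or `volume3d`).
#' @param node_spacing control point spacing in mm (length 1 or 3). The
#'   conventional choice is 8 voxels of the image the deformation acts on.
#' @param displacements optional initial displacement array
#'   `(nc1, nc2, nc3, 3)` in mm (default zero).
#' @return An object of class `control_grid` with fields `disp`, `origin`,
#'   `spacing`, `dims`.
#' @export
make_control_grid <- function(grid, node_spacing, displacements = NULL) {
  grid <- vol_grid(grid)
  cs <- rep(as.numeric(node_spacing), length.out = 3)
  extent <- (grid$shape - 1) * grid$spacing
  dims <- as.integer(ceiling(extent / cs) + 5)
  origin <- grid$origin - 2 * cs
  if (is.null(displacements)) displacements <- array(0, c(dims, 3))
  stopifnot(all(dim(displacements) == c(dims, 3)))
  structure(list(disp = displacements, origin = origin, spacing = cs, dims = dims),
            class = "control_grid")
}

#' @export
print.control_grid <- function(x, ...) {
  cat(sprintf("control_grid: %s nodes @ %s mm, max |displacement| %.3g mm\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              max(abs(x$disp))))
  invisible(x)
}

cpg_like <- function(cpg, disp) {
  cpg$disp <- disp
  cpg
}

#' Evaluate a free-form deformation as a dense displacement field
#'
#' Computes the voxel-wise displacement field of the cubic B-spline free-form
#' deformation defined by a control point grid: at every voxel center the
#' tensor-product of 1-D cubic B-spline basis values weights the displacements
#' of the 4x4x4 surrounding nodes. The result is C2-smooth and linear in the
#' node displacements.
#'
#' @param cpg a [make_control_grid()] object.
#' @param grid target grid (`grid3d` or `volume3d`).
#' @return a `dense_dvf`: numeric array `(nx, ny, nz, 3)` of mm displacements
#'   with `spacing`/`origin` attributes.
#' @export
ffd_to_dvf <- function(cpg, grid) {
  grid <- vol_grid(grid)
  d <- cpp_ffd_to_dvf(as.numeric(cpg$disp), cpg$dims, cpg$origin, cpg$spacing,
                      grid$shape, grid$spacing, grid$origin)
  dense_dvf(array(d, c(grid$shape, 3)), grid$spacing, grid$origin)
}

#' Construct a dense displacement field object
#'
#' The convention throughout the package is the pull-back mapping used by the
#' resampling: the frame-t image is `I_t(x) = I_0(x + D_t(x))`, i.e. the
#' field maps acquisition-frame coordinates to reference-sampling offsets.
#'
#' @param data numeric array `(nx, ny, nz, 3)`, displacements in mm.
#' @param spacing,origin grid metadata of the field's domain.
#' @return an object of class `dense_dvf`.
#' @export
dense_dvf <- function(data, spacing, origin = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4, dim(data)[4] == 3)
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (is.null(origin)) origin <- -(dim(data)[1:3] - 1) * spacing / 2
  structure(data, spacing = spacing, origin = as.numeric(origin),
            class = c("dense_dvf", "array"))
}

#' @export
print.dense_dvf <- function(x, ...) {
  mag <- sqrt(x[, , , 1]^2 + x[, , , 2]^2 + x[, , , 3]^2)
  cat(sprintf("dense_dvf: %s voxels, |D| mean %.3g mm, max %.3g mm\n",
              paste(dim(x)[1:3], collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

dvf_grid <- function(dvf) grid3d(dim(dvf)[1:3], attr(dvf, "spacing"), attr(dvf, "origin"))

zero_dvf <- function(grid) {
  grid <- vol_grid(grid)
  dense_dvf(array(0, c(grid$shape, 3)), grid$spacing, grid$origin)
}

#' Adjoint of the FFD evaluation
#'
#' Maps a voxel-wise 3-vector field (a gradient with respect to the dense
#' DVF) back to control-point space: the exact transpose of the linear map
#' computed by [ffd_to_dvf()], as required by the chain rule of the
#' projection-domain loss gradient.
#'
#' @param voxel_field numeric array `(nx, ny, nz, 3)` on `grid`.
#' @param cpg a `control_grid` providing the node layout.
#' @param grid the grid `voxel_field` lives on.
#' @return a `control_grid` whose `disp` holds the accumulated node gradient.
#' @export
dvf_adjoint_to_cpg <- function(voxel_field, cpg, grid) {
  grid <- vol_grid(grid)
  stopifnot(all(dim(voxel_field) == c(grid$shape, 3)))
  g <- cpp_ffd_adjoint(as.numeric(voxel_field), grid$shape, grid$spacing,
                       grid$origin, cpg$dims, cpg$origin, cpg$spacing)
  cpg_like(cpg, array(g, c(cpg$dims, 3)))
}

#' Warp an image by a dense displacement field
#'
#' Resamples `vol` by the pull-back convention `out(x) = vol(x + D(x))`.
#' `interp = "linear"` uses trilinear interpolation; `interp = "cubic"` uses
#' cubic B-spline interpolation (with prefiltering), which makes the result
#' continuously differentiable in the displacements — the mode used by the
#' model-fitting loss. Samples falling outside the volume return `fill`.
#'
#' @param vol a [volume3d()].
#' @param dvf a `dense_dvf` on the grid of `vol`.
#' @param interp `"linear"` or `"cubic"`.
#' @param fill value for out-of-domain samples (default the null value `NA`).
#' @return a [volume3d()].
#' @export
warp_image <- function(vol, dvf, interp = c("linear", "cubic"), fill = NA_real_) {
  interp <- match.arg(interp)
  g <- vol_grid(vol)
  check_dvf_grid(dvf, g)
  img <- as.numeric(vol)
  mode <- 0L
  if (interp == "cubic") {
    img[!is.finite(img)] <- 0
    img <- cpp_bspline_prefilter(img, g$shape)
    mode <- 1L
  }
  w <- cpp_warp(img, g$shape, g$spacing, g$origin, as.numeric(dvf),
                mode, fill, FALSE, FALSE)
  volume3d(array(w$value, g$shape), g$spacing, g$origin)
}

check_dvf_grid <- function(dvf, grid) {
  grid <- vol_grid(grid)
  if (!all(dim(dvf)[1:3] == grid$shape) ||
      max(abs(attr(dvf, "spacing") - grid$spacing)) > 1e-9 ||
      max(abs(attr(dvf, "origin") - grid$origin)) > 1e-6)
    stop("displacement field grid does not match the volume grid")
  invisible(TRUE)
}

#' Intensity gradient at warped sample positions
#'
#' The chain-rule factor of the projection-domain loss gradient with respect
#' to the dense DVF: the spatial gradient of `vol` evaluated at the warped
#' sample positions `x + D(x)`, in intensity per mm. In `"cubic"` mode this is
#' the analytic derivative of the B-spline interpolant (exactly consistent
#' with the `"cubic"` warp); in `"linear"` mode a half-voxel secant of the
#' trilinear interpolant, which reduces to central differences of `vol` when
#' the displacement is zero.
#'
#' @inheritParams warp_image
#' @return numeric array `(nx, ny, nz, 3)`.
#' @export
intensity_gradient_term <- function(vol, dvf, interp = c("linear", "cubic")) {
  interp <- match.arg(interp)
  g <- vol_grid(vol)
  check_dvf_grid(dvf, g)
  img <- as.numeric(vol)
  mode <- 0L
  if (interp == "cubic") {
    img[!is.finite(img)] <- 0
    img <- cpp_bspline_prefilter(img, g$shape)
    mode <- 1L
  }
  w <- cpp_warp(img, g$shape, g$spacing, g$origin, as.numeric(dvf),
                mode, 0, FALSE, TRUE)
  array(c(w$gx, w$gy, w$gz), c(g$shape, 3))
}

#' Numerically invert a displacement field
#'
#' Fixed-point inversion of the pull-back field: iterates
#' `Dinv <- -D(x + Dinv(x))` until the mean update is below `tol` voxels.
#' Used by the motion-compensated FDK to obtain the reference-to-frame
#' mapping from the stored frame-to-reference field.
#'
#' @param dvf a `dense_dvf`.
#' @param max_iter iteration cap.
#' @param tol stopping tolerance: mean displacement update in voxels.
#' @return a `dense_dvf` approximating the inverse mapping.
#' @export
invert_dvf <- function(dvf, max_iter = 20L, tol = 0.01) {
  g <- dvf_grid(dvf)
  nvox <- prod(g$shape)
  d <- as.numeric(dvf)
  inv <- numeric(3 * nvox)
  mean_sp <- mean(g$spacing)
  for (it in seq_len(max_iter)) {
    new <- -cpp_compose_dvf(d, g$shape, g$spacing, inv)
    upd <- mean(abs(new - inv)) / mean_sp
    inv <- new
    if (upd < tol) break
  }
  dense_dvf(array(inv, c(g$shape, 3)), g$spacing, g$origin)
}

#' Refine a control point grid to half the node spacing
#'
#' Exact dyadic cubic B-spline subdivision: the refined grid (same origin,
#' half the spacing, `2n - 1` nodes per axis) represents the identical
#' deformation. Used when advancing a resolution level.
#'
#' @param cpg a `control_grid`.
#' @return a `control_grid` at half the node spacing.
#' @export
refine_control_grid <- function(cpg) {
  a <- as.numeric(cpg$disp)
  d <- cpg$dims
  for (axis in 0:2) {
    a <- cpp_refine_axis(a, d, axis)
    d[axis + 1] <- 2L * d[axis + 1] - 1L
  }
  structure(list(disp = array(a, c(d, 3)), origin = cpg$origin,
                 spacing = cpg$spacing / 2, dims = d),
            class = "control_grid")
}
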