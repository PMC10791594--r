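#' Cone-beam forward projection
#'
#' Computes the line integrals of a volume along the rays from the source to
#' each detector pixel for one gantry position (the acquisition operator
#' applied to the volume). Sampling is trilinear along the ray with a step of
#' half the smallest voxel spacing; null (`NA`) voxels contribute zero.
#'
#' @param vol a [volume3d()].
#' @param geom a [cbct_geometry()].
#' @param frame_index 1-based projection index into `geom`.
#' @return numeric matrix `(nu, nv)` of line integrals (dimensionless).
#' @seealso [back_project()] for the exact adjoint,
#'   [detector_validity_mask()] for the FOV validity mask.
#' @export
forward_project <- function(vol, geom, frame_index) {
  validate_geometry(geom)
  g <- vol_grid(vol)
  frame_index <- check_frame(frame_index, geom)
  step <- min(g$spacing) / 2
  cpp_forward_project(as.numeric(vol), g$shape, g$spacing, g$origin,
                      geom$sid, geom$sdd, geom$nu, geom$nv, geom$du, geom$dv,
                      deg2rad(geom$angles[frame_index]), step)
}

#' Adjoint cone-beam backprojection
#'
#' The exact adjoint of [forward_project()] with respect to the standard
#' (unweighted) inner products: the same ray walk, scattering detector values
#' into the volume with the same trilinear weights. This is the transport
#' operator used in the model-fit gradient chain, not the filtered/weighted
#' backprojection used by FDK (see [fdk_reconstruct()]).
#'
#' @param proj numeric matrix `(nu, nv)`.
#' @param geom a [cbct_geometry()].
#' @param frame_index 1-based projection index.
#' @param target_grid a `grid3d` (or `volume3d`) defining the output grid.
#' @return a [volume3d()].
#' @export
back_project <- function(proj, geom, frame_index, target_grid) {
  validate_geometry(geom)
  g <- vol_grid(target_grid)
  frame_index <- check_frame(frame_index, geom)
  if (!all(dim(proj) == c(geom$nu, geom$nv)))
    stop("projection dimensions do not match the detector description")
  step <- min(g$spacing) / 2
  v <- cpp_back_project(proj, g$shape, g$spacing, g$origin,
                        geom$sid, geom$sdd, geom$nu, geom$nv, geom$du, geom$dv,
                        deg2rad(geom$angles[frame_index]), step)
  volume3d(array(v, g$shape), g$spacing, g$origin)
}

#' Detector validity mask for FOV-truncated rays
#'
#' Marks detector pixels whose rays stay inside the FOV cylinder while
#' crossing the reconstruction grid. Pixels whose rays traverse null
#' (out-of-FOV) voxels are invalid and are excluded from the similarity loss.
#'
#' @param geom a [cbct_geometry()].
#' @param frame_index 1-based projection index.
#' @param grid the reconstruction grid (`grid3d` or `volume3d`).
#' @param fov_radius FOV cylinder radius in mm (default: inscribed cylinder).
#' @return logical matrix `(nu, nv)`.
#' @export
detector_validity_mask <- function(geom, frame_index, grid, fov_radius = NULL) {
  validate_geometry(geom)
  g <- vol_grid(grid)
  frame_index <- check_frame(frame_index, geom)
  if (is.null(fov_radius)) fov_radius <- default_fov_radius(g)
  cpp_detector_validity(g$shape, g$spacing, g$origin,
                        geom$sid, geom$sdd, geom$nu, geom$nv, geom$du, geom$dv,
                        deg2rad(geom$angles[frame_index]), fov_radius)
}

check_frame <- function(frame_index, geom) {
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != 1 || is.na(frame_index) ||
      frame_index < 1 || frame_index > n_frames(geom))
    stop("frame_index out of range [1, ", n_frames(geom), "]")
  frame_index
}

deg2rad <- function(x) x * pi / 180
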