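#' Read and write volumes as NIfTI
#'
#' Volumes are stored as NIfTI (double precision) with the voxel spacing in
#' `pixdim` and the world coordinate of the first voxel center in the qform
#' offset; the numeric payload round-trips bit-identically. Null (`NA`)
#' voxels are stored as NaN.
#'
#' @param vol a [volume3d()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume3d()].
#' @export
write_volume <- function(vol, path) {
  g <- vol_grid(vol)
  arr <- array(as.numeric(vol), g$shape)
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- g$spacing
  RNifti::`qform<-`(im, structure(rbind(cbind(diag(g$spacing), g$origin),
                                        c(0, 0, 0, 1)), code = 2L)) -> im
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(im)
  spacing <- RNifti::pixdim(im)[1:3]
  origin <- c(h$qoffset_x, h$qoffset_y, h$qoffset_z)
  volume3d(array(as.numeric(im), dim(im)[1:3]), spacing, origin)
}

#' Read and write dense displacement fields
#'
#' Stored as 4D NIfTI with the three displacement components (mm) in the
#' fourth dimension, in the pull-back convention (`I_t(x) = I_0(x + D(x))`).
#'
#' @param dvf a `dense_dvf`.
#' @param path file path.
#' @return `read_dvf` returns a `dense_dvf`.
#' @export
write_dvf <- function(dvf, path) {
  g <- dvf_grid(dvf)
  im <- RNifti::asNifti(array(as.numeric(dvf), c(g$shape, 3)))
  RNifti::pixdim(im) <- c(g$spacing, 1)
  RNifti::`qform<-`(im, structure(rbind(cbind(diag(g$spacing), g$origin),
                                        c(0, 0, 0, 1)), code = 2L)) -> im
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  im <- RNifti::readNifti(path)
  h <- RNifti::niftiHeader(im)
  d <- dim(im)
  if (length(d) != 4 || d[4] != 3) stop("not a 3-component displacement field")
  dense_dvf(array(as.numeric(im), d), RNifti::pixdim(im)[1:3],
            c(h$qoffset_x, h$qoffset_y, h$qoffset_z))
}

#' Read and write projection stacks
#'
#' The image payload is a 3D NIfTI (u, v, frame); the acquisition geometry
#' travels in a sidecar JSON (same path with extension `.json`) written by
#' [write_geometry()].
#'
#' @param projs a [projection_stack()].
#' @param path image file path (`.nii` or `.nii.gz`); the geometry sidecar
#'   derives from it.
#' @return `read_projections` returns a [projection_stack()].
#' @export
write_projections <- function(projs, path) {
  im <- RNifti::asNifti(projs$data)
  RNifti::pixdim(im) <- c(projs$geometry$du, projs$geometry$dv, 1)
  RNifti::writeNifti(im, path)
  write_geometry(projs$geometry, sidecar_path(path))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  im <- RNifti::readNifti(path)
  geom <- read_geometry(sidecar_path(path))
  projection_stack(array(as.numeric(im), dim(im)[1:3]), geom)
}

sidecar_path <- function(path) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' Read and write surrogate signals as CSV
#'
#' Columns: `time_s`, then one column per signal.
#'
#' @param S surrogate matrix (`N_t x N_s`).
#' @param times per-frame timestamps (seconds).
#' @param path file path.
#' @return `read_signals` returns a list with `S` (matrix) and `times`.
#' @export
write_signals <- function(S, times, path) {
  S <- as.matrix(S)
  df <- data.frame(time_s = times, S)
  names(df) <- c("time_s", colnames(S) %||% paste0("s", seq_len(ncol(S))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signals
#' @export
read_signals <- function(path) {
  df <- read.csv(path)
  if (!"time_s" %in% names(df)) stop("signals CSV must have a time_s column")
  S <- as.matrix(df[setdiff(names(df), "time_s")])
  list(S = S, times = df$time_s)
}

#' Save and load a fitted motion model
#'
#' The model container (components, node layout, surrogates, geometry, fit
#' log, configuration) is serialized with R's native RDS format.
#'
#' @param model a `moco_model` or `correspondence_model`.
#' @param path file path (`.rds`).
#' @return `read_model` returns the model object.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)

#' Convert raw-intensity projections to line integrals
#'
#' Real scanners record transmitted intensity; line integrals are obtained by
#' `-log(I / I_flat)`. Simulated data in this package is already in the
#' line-integral domain.
#'
#' @param raw array of raw intensities.
#' @param flat flat-field (unattenuated) intensity; default the max of `raw`.
#' @return array of line integrals (non-negative).
#' @export
intensity_to_line_integral <- function(raw, flat = NULL) {
  if (is.null(flat)) flat <- max(raw)
  if (any(raw <= 0)) stop("raw intensities must be positive")
  pmax(-log(raw / flat), 0)
}
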