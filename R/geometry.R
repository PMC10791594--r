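#' Cone-beam CT scan geometry
#'
#' Describes a circular-trajectory cone-beam acquisition: source-to-isocenter
#' and source-to-detector distances, a flat detector panel, and per-projection
#' gantry angles and timestamps. The gantry rotates in the axial (x-y) plane
#' about the z axis; the detector is centered on the source-isocenter line
#' (no lateral panel offset).
#'
#' @param n_proj number of projections.
#' @param sid source-to-isocenter distance (mm).
#' @param sdd source-to-detector distance (mm).
#' @param detector_px detector size in pixels, length 2 (u = in-plane, v = axial).
#' @param detector_spacing detector pixel spacing (mm), length 2.
#' @param arc total gantry arc in degrees (default a full rotation).
#' @param fps acquisition frame rate (projections per second).
#' @param start_angle gantry angle of the first projection (degrees).
#' @param angles,times optional explicit per-projection gantry angles (degrees)
#'   and timestamps (seconds); override `arc`/`fps`.
#'
#' @details The defaults mirror a conventional Elekta-style thorax protocol:
#' SID 1000 mm, SDD 1536 mm, 310 projections over 360 degrees at 5.4 frames
#' per second (a one-minute scan).
#'
#' @return An object of class `scan_geometry`.
#' @export
cbct_geometry <- function(n_proj = 310L, sid = 1000, sdd = 1536,
                          detector_px = c(128L, 128L),
                          detector_spacing = c(3.2, 3.2),
                          arc = 360, fps = 5.4, start_angle = 0,
                          angles = NULL, times = NULL) {
  n_proj <- as.integer(n_proj)
  if (is.null(angles))
    angles <- start_angle + seq(0, arc, length.out = n_proj + 1L)[seq_len(n_proj)]
  if (is.null(times))
    times <- (seq_len(n_proj) - 1L) / fps
  g <- structure(list(
    sid = as.numeric(sid), sdd = as.numeric(sdd),
    nu = as.integer(detector_px[1]), nv = as.integer(detector_px[2]),
    du = as.numeric(detector_spacing[1]), dv = as.numeric(detector_spacing[2]),
    angles = as.numeric(angles), times = as.numeric(times)
  ), class = "scan_geometry")
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  if (!(g$sdd > g$sid && g$sid > 0))
    stop("scan geometry requires sdd > sid > 0")
  if (length(g$angles) != length(g$times))
    stop("angles and times must have one entry per projection")
  if (g$nu < 1 || g$nv < 1 || g$du <= 0 || g$dv <= 0)
    stop("invalid detector description")
  if (any(!is.finite(g$angles)) || any(!is.finite(g$times)))
    stop("non-finite angles or times")
  invisible(g)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("Cone-beam scan geometry: %d projections\n", n_frames(x)))
  cat(sprintf("  SID %.1f mm, SDD %.1f mm\n", x$sid, x$sdd))
  cat(sprintf("  detector %d x %d px @ %.3g x %.3g mm\n", x$nu, x$nv, x$du, x$dv))
  cat(sprintf("  angles %.1f..%.1f deg, duration %.1f s\n",
              min(x$angles), max(x$angles), diff(range(x$times))))
  invisible(x)
}

#' Number of projection frames in a geometry or projection stack
#' @param x a `scan_geometry` or `projection_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "projection_stack")) x <- x$geometry
  length(x$angles)
}

#' Read/write scan geometry as JSON
#'
#' The geometry is stored as a flat JSON document (distances, detector shape
#' and spacing, per-frame angle and time arrays).
#'
#' @param geom a `scan_geometry`.
#' @param path file path.
#' @return `read_geometry` returns a `scan_geometry`; `write_geometry` its
#'   path, invisibly.
#' @export
write_geometry <- function(geom, path) {
  validate_geometry(geom)
  obj <- list(sid = geom$sid, sdd = geom$sdd,
              detector_px = c(geom$nu, geom$nv),
              detector_spacing = c(geom$du, geom$dv),
              angles_deg = geom$angles, times_s = geom$times)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sid", "sdd", "detector_px", "detector_spacing", "angles_deg", "times_s"))
    if (is.null(obj[[f]])) stop("geometry JSON is missing field '", f, "'")
  cbct_geometry(n_proj = length(obj$angles_deg), sid = obj$sid, sdd = obj$sdd,
                detector_px = obj$detector_px,
                detector_spacing = obj$detector_spacing,
                angles = obj$angles_deg, times = obj$times_s)
}

# geometry at a coarser resolution level: detector pixels pooled by `factor`
# (projection images are block-averaged by the same factor)
level_geometry <- function(geom, factor) {
  stopifnot(factor >= 1, geom$nu %% factor == 0, geom$nv %% factor == 0)
  g <- geom
  g$nu <- as.integer(geom$nu / factor)
  g$nv <- as.integer(geom$nv / factor)
  g$du <- geom$du * factor
  g$dv <- geom$dv * factor
  g
}
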