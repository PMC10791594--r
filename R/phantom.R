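#' Analytic 4D thorax phantom specification
#'
#' A piecewise-constant attenuation phantom built from ellipsoids: a body
#' (soft tissue, approximately water), two lungs (low-density air-tissue mix),
#' a denser spine rod, and a spherical tumor in the lower left lung. Axes:
#' x = left-right, y = anterior-posterior (+y anterior), z = inferior-superior
#' (+z superior, rotation axis); the isocenter is the world origin.
#'
#' @param grid phantom grid (`grid3d`); default 128^3 at 2 mm. Set
#'   `full_scale = TRUE` for the full-scale 375 x 375 x 343 grid at
#'   1 mm.
#' @param full_scale use the full-scale grid.
#' @param tumor_center,tumor_radius tumor sphere (mm); default a 15 mm-radius
#'   sphere in the lower part of the left lung.
#' @param mu attenuation coefficients (per mm) for body, lung, tumor, spine.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid3d(128L, 2), full_scale = FALSE,
                         tumor_center = c(-48, 0, -35), tumor_radius = 15,
                         mu = c(body = 0.02, lung = 0.005,
                                tumor = 0.02, spine = 0.035)) {
  if (full_scale) grid <- grid3d(c(375L, 375L, 343L), 1)
  grid <- vol_grid(grid)
  spec <- structure(list(
    grid = grid,
    body = list(center = c(0, 0, 0), semi = c(110, 85, 120)),
    lungs = list(list(center = c(-48, 0, 15), semi = c(38, 52, 82)),
                 list(center = c(48, 0, 15), semi = c(38, 52, 82))),
    spine = list(center_xy = c(0, -62), radius = 13, half_height = 115),
    tumor = list(center = as.numeric(tumor_center),
                 radius = as.numeric(tumor_radius)),
    mu = mu
  ), class = "phantom_spec")
  if (any(mu < 0)) stop("attenuations must be non-negative")
  lungs_ok <- vapply(spec$lungs, function(l) {
    shr <- l$semi - spec$tumor$radius
    all(shr > 0) && sum(((spec$tumor$center - l$center) / shr)^2) <= 1
  }, logical(1))
  if (!any(lungs_ok)) stop("tumor is not strictly inside a lung")
  spec
}

inside_ellipsoid <- function(grid, center, semi) {
  x <- (axis_coords(grid, 1) - center[1]) / semi[1]
  y <- (axis_coords(grid, 2) - center[2]) / semi[2]
  z <- (axis_coords(grid, 3) - center[3]) / semi[3]
  outer(outer(x^2, y^2, "+"), z^2, "+") <= 1
}

#' Build the reference (time-average) phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` (a [volume3d()] of attenuation per mm)
#'   and `tumor_mask` (logical [volume3d()]).
#' @export
make_reference_phantom <- function(spec) {
  g <- spec$grid
  vol <- array(0, g$shape)
  vol[inside_ellipsoid(g, spec$body$center, spec$body$semi)] <- spec$mu[["body"]]
  x <- axis_coords(g, 1); y <- axis_coords(g, 2); z <- axis_coords(g, 3)
  sp <- spec$spine
  spine2 <- outer((x - sp$center_xy[1])^2, (y - sp$center_xy[2])^2, "+") <= sp$radius^2
  spine <- array(rep(spine2, g$shape[3]), g$shape) &
    array(rep(abs(z) <= sp$half_height, each = g$shape[1] * g$shape[2]), g$shape)
  vol[spine & vol > 0] <- spec$mu[["spine"]]
  for (l in spec$lungs)
    vol[inside_ellipsoid(g, l$center, l$semi)] <- spec$mu[["lung"]]
  tum <- inside_ellipsoid(g, spec$tumor$center, rep(spec$tumor$radius, 3))
  vol[tum] <- spec$mu[["tumor"]]
  list(volume = volume3d(vol, g$spacing, g$origin),
       tumor_mask = volume3d(tum, g$spacing, g$origin))
}

#' Generate a pair of breathing traces
#'
#' Produces the diaphragm (superior-inferior) and chest-surface
#' (anterior-posterior) breathing traces that drive the simulation, sampled
#' at the projection timestamps. The waveform is the classic
#' `cos^4` respiratory shape (long exhale rest, short inhale). In the
#' `regular` regime the two traces are in phase with fixed amplitude; in the
#' `irregular` regime the chest trace leads by a quarter cycle (hysteresis)
#' and both traces have per-cycle random amplitude variation.
#'
#' @param regime `"regular"` or `"irregular"`.
#' @param n_t number of samples (projections).
#' @param frame_rate_hz sampling rate; default 5.4 fps.
#' @param seed RNG seed for the per-cycle variability.
#' @param period_s breathing period (seconds).
#' @param diaphragm_amplitude,chest_amplitude peak-to-peak amplitudes in mm.
#' @param phase_offset_deg chest lead in the irregular regime (degrees of a
#'   breathing cycle).
#' @param variability fractional per-cycle amplitude variation in the
#'   irregular regime.
#' @return a list of class `breathing_traces` with `s_diaphragm`, `s_chest`
#'   ([resp_trace()]s), the regime and the generating parameters.
#' @export
make_breathing_traces <- function(regime = c("regular", "irregular"),
                                  n_t = 310L, frame_rate_hz = 5.4, seed = 0L,
                                  period_s = 4,
                                  diaphragm_amplitude = 30,
                                  chest_amplitude = 7,
                                  phase_offset_deg = 90,
                                  variability = 0.3) {
  regime <- match.arg(regime)
  if (n_t < 2) stop("need at least 2 time points")
  tt <- (seq_len(n_t) - 1L) / frame_rate_hz
  phase <- 2 * pi * tt / period_s
  wave <- function(ph) cos(ph / 2)^4   # period 2*pi in ph, range [0, 1]
  if (regime == "regular") {
    off <- 0
    amp_d <- rep(1, n_t)
    amp_c <- rep(1, n_t)
    # a whiff of quadrature keeps the pair non-degenerate but tightly in phase
    sd_ <- wave(phase) + 0.04 * wave(phase + pi / 2)
    sc_ <- wave(phase)
  } else {
    off <- deg2rad(phase_offset_deg)
    cyc <- floor(phase / (2 * pi))
    rng <- local_rng(seed)
    ncyc <- max(cyc) + 1L
    ad <- 1 + variability * rng$runif(ncyc, -1, 1)
    ac <- 1 + variability * rng$runif(ncyc, -1, 1)
    amp_d <- ad[cyc + 1L]
    amp_c <- ac[cyc + 1L]
    sd_ <- amp_d * wave(phase)
    sc_ <- amp_c * wave(phase + off)
  }
  d <- diaphragm_amplitude * (sd_ - mean(sd_))
  ch <- chest_amplitude * (sc_ - mean(sc_))
  structure(list(
    s_diaphragm = resp_trace(d, tt, "diaphragm_SI"),
    s_chest = resp_trace(ch, tt, "chest_AP"),
    regime = regime,
    phase_offset_deg = if (regime == "regular") 0 else phase_offset_deg,
    variability = if (regime == "regular") 0 else variability,
    period_s = period_s, seed = seed
  ), class = "breathing_traces")
}

# private RNG stream that leaves the global .Random.seed untouched
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = function(...) draw(stats::runif, ...),
       rnorm = function(...) draw(stats::rnorm, ...),
       sample = function(...) draw(base::sample, ...))
}

#' Ground-truth motion for the simulated scan
#'
#' Builds the per-frame ground-truth displacement fields driven by the
#' breathing traces. Mechanism `"model_class"` (default) constructs a fixed
#' ground-truth correspondence model: two control-point-grid components, a
#' dominant superior-inferior field peaking at the diaphragm and an
#' anterior-posterior field peaking at the chest surface, driven linearly by
#' the normalized traces — so the model-fitting problem has an exact solution
#' in its own transformation class. Mechanism `"analytic"` evaluates the same
#' smooth weight fields densely without the B-spline parameterisation. Both
#' mechanisms scale amplitudes down if needed so the deformations stay
#' invertible (positive Jacobian).
#'
#' @param traces a [make_breathing_traces()] object.
#' @param spec a [phantom_spec()].
#' @param mechanism `"model_class"` or `"analytic"`.
#' @param node_spacing control point spacing in mm for the model-class
#'   mechanism; default 16 phantom voxels (8 voxels of a half-resolution
#'   image, matching the finest fitting level).
#' @return a list of class `gt_motion` with the normalized driving signals
#'   `S` (`N_t x 2`), a `dvf_fun(t, grid)` evaluator, the generating
#'   component fields, and Jacobian bookkeeping.
#' @export
make_gt_motion <- function(traces, spec, mechanism = c("model_class", "analytic"),
                           node_spacing = NULL) {
  mechanism <- match.arg(mechanism)
  g <- spec$grid
  if (is.null(node_spacing)) node_spacing <- 16 * min(g$spacing)
  S <- surrogate_matrix(traces$s_diaphragm, traces$s_chest)
  # mm of displacement per unit normalized signal reproduces the raw traces
  a_si <- sd(traces$s_diaphragm$values)
  a_ap <- sd(traces$s_chest$values)
  zd <- min(vapply(spec$lungs, function(l) l$center[3] - l$semi[3], 0))  # diaphragm
  ych <- spec$body$center[2] + spec$body$semi[2]                        # chest wall
  w_si <- function(x, y, z)
    a_si * exp(-((z - zd)^2) / (2 * 70^2)) * exp(-(x^2 + y^2) / 120^2)
  w_ap <- function(x, y, z)
    a_ap * exp(-((y - ych)^2) / (2 * 50^2)) * exp(-(x^2 + (z - 0)^2) / 150^2)
  # invertibility guard: bound the worst-case field gradient analytically
  smax <- max(abs(S))
  slope <- smax * max(a_si * exp(-0.5) / 70, a_ap * exp(-0.5) / 50)
  scale <- if (slope > 0.6) 0.6 / slope else 1
  if (mechanism == "model_class") {
    tmpl <- make_control_grid(g, node_spacing)
    nx <- axis_coords_cpg(tmpl, 1); ny <- axis_coords_cpg(tmpl, 2)
    nz <- axis_coords_cpg(tmpl, 3)
    pts <- expand.grid(x = nx, y = ny, z = nz)
    c1 <- array(0, c(tmpl$dims, 3))
    c1[, , , 3] <- scale * w_si(pts$x, pts$y, pts$z)
    c2 <- array(0, c(tmpl$dims, 3))
    c2[, , , 2] <- scale * w_ap(pts$x, pts$y, pts$z)
    comp <- list(cpg_like(tmpl, c1), cpg_like(tmpl, c2))
    dvf_fun <- function(t, grid = g) {
      cp <- cpg_like(tmpl, S[t, 1] * c1 + S[t, 2] * c2)
      ffd_to_dvf(cp, grid)
    }
  } else {
    comp <- list(si = w_si, ap = w_ap, scale = scale)
    dvf_fun <- function(t, grid = g) {
      grid <- vol_grid(grid)
      x <- axis_coords(grid, 1); y <- axis_coords(grid, 2); z <- axis_coords(grid, 3)
      pts <- expand.grid(x = x, y = y, z = z)
      d <- array(0, c(grid$shape, 3))
      d[, , , 3] <- scale * S[t, 1] * w_si(pts$x, pts$y, pts$z)
      d[, , , 2] <- scale * S[t, 2] * w_ap(pts$x, pts$y, pts$z)
      dense_dvf(d, grid$spacing, grid$origin)
    }
  }
  structure(list(mechanism = mechanism, S = S, traces = traces,
                 components = comp, grid = g, dvf_fun = dvf_fun,
                 amplitude_scale = scale,
                 node_spacing = node_spacing),
            class = "gt_motion")
}

axis_coords_cpg <- function(cpg, axis)
  cpg$origin[axis] + (seq_len(cpg$dims[axis]) - 1) * cpg$spacing[axis]

#' Ground-truth tumor mask at one frame
#'
#' Warps the reference tumor mask by the frame's ground-truth field
#' (trilinear pull-back warp of the indicator, thresholded at 0.5).
#'
#' @param motion a [make_gt_motion()] object.
#' @param t frame index.
#' @param ref_mask reference tumor mask (logical [volume3d()]).
#' @return logical [volume3d()].
#' @export
gt_tumor_mask <- function(motion, t, ref_mask) {
  warp_mask(ref_mask, motion$dvf_fun(t, vol_grid(ref_mask)))
}

# trilinear warp of a binary mask, thresholded at 0.5
warp_mask <- function(mask, dvf) {
  g <- vol_grid(mask)
  w <- warp_image(volume3d(mask * 1, g$spacing, g$origin), dvf,
                  interp = "linear", fill = 0)
  volume3d(array(w >= 0.5, g$shape), g$spacing, g$origin)
}

#' Simulate a dynamic cone-beam scan of the phantom
#'
#' For each frame, warps the reference phantom by the frame's ground-truth
#' field (pull-back) and forward-projects it at the frame's gantry angle.
#'
#' @param phantom reference volume (a [volume3d()], e.g. from
#'   [make_reference_phantom()]).
#' @param motion a [make_gt_motion()] object (frame count must match the
#'   geometry).
#' @param geom a [cbct_geometry()].
#' @return a [projection_stack()].
#' @export
simulate_scan <- function(phantom, motion, geom) {
  nt <- n_frames(geom)
  if (nrow(motion$S) != nt)
    stop("motion has ", nrow(motion$S), " frames but geometry describes ", nt)
  g <- vol_grid(phantom)
  arr <- array(0, c(geom$nu, geom$nv, nt))
  for (t in seq_len(nt)) {
    it <- warp_image(phantom, motion$dvf_fun(t, g), interp = "linear", fill = 0)
    arr[, , t] <- forward_project(it, geom, t)
  }
  projection_stack(arr, geom)
}

#' Simulate a complete study case
#'
#' One call producing everything the fitting and evaluation pipeline needs:
#' phantom, traces, ground-truth motion, and the simulated projection stack.
#'
#' @param regime breathing regime, see [make_breathing_traces()].
#' @param spec a [phantom_spec()].
#' @param geom a [cbct_geometry()]; frame count sets the trace length.
#' @param seed RNG seed for trace variability.
#' @param mechanism ground-truth motion mechanism, see [make_gt_motion()].
#' @param ... further arguments to [make_breathing_traces()].
#' @return list of class `moco_sim` with fields `spec`, `phantom`,
#'   `tumor_mask`, `traces`, `motion`, `projections`, `geometry`.
#' @export
simulate_case <- function(regime = "regular", spec = phantom_spec(),
                          geom = cbct_geometry(), seed = 0L,
                          mechanism = "model_class", ...) {
  ref <- make_reference_phantom(spec)
  fps <- 1 / mean(diff(geom$times))
  traces <- make_breathing_traces(regime, n_t = n_frames(geom),
                                  frame_rate_hz = fps, seed = seed, ...)
  motion <- make_gt_motion(traces, spec, mechanism)
  projs <- simulate_scan(ref$volume, motion, geom)
  structure(list(spec = spec, phantom = ref$volume, tumor_mask = ref$tumor_mask,
                 traces = traces, motion = motion, projections = projs,
                 geometry = geom),
            class = "moco_sim")
}
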