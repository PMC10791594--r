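#' Reconstruction configuration
#'
#' @param grid output grid (`grid3d` or `volume3d`).
#' @param filter_window apodisation of the ramp filter: `"hann"` (default) or
#'   `"ramlak"` (no window).
#' @param fov_radius FOV cylinder radius in mm; voxels outside are set to the
#'   null value. Default: the largest cylinder inscribed in the grid.
#' @return a list of class `recon_config`.
#' @export
recon_config <- function(grid, filter_window = c("hann", "ramlak"),
                         fov_radius = NULL) {
  grid <- vol_grid(grid)
  if (is.null(fov_radius)) fov_radius <- default_fov_radius(grid)
  structure(list(grid = grid, filter_window = match.arg(filter_window),
                 fov_radius = fov_radius),
            class = "recon_config")
}

# frequency response of the band-limited ramp kernel (spacing ds), apodised
ramp_filter_freq <- function(n_pad, ds, window = "hann") {
  h <- numeric(n_pad)
  idx <- seq_len(n_pad) - 1L
  m <- ifelse(idx <= n_pad / 2, idx, idx - n_pad)  # circular offsets
  h[m == 0] <- 1 / (4 * ds^2)
  odd <- (m %% 2) != 0
  h[odd] <- -1 / (pi * m[odd] * ds)^2
  H <- Re(fft(h))
  if (window == "hann") {
    f <- pmin(idx, n_pad - idx) / (n_pad / 2)  # 0..1, Nyquist at 1
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  H
}

# cosine weighting + ramp filtering of one projection, in isocenter-scaled
# detector coordinates; includes the fan/cone-beam 1/2 factor
fdk_filter_projection <- function(proj, geom, H = NULL, window = "hann") {
  nu <- geom$nu; nv <- geom$nv
  ds <- geom$du * geom$sid / geom$sdd
  dvs <- geom$dv * geom$sid / geom$sdd
  s <- (seq_len(nu) - (nu + 1) / 2) * ds
  v <- (seq_len(nv) - (nv + 1) / 2) * dvs
  w <- geom$sid / sqrt(geom$sid^2 + outer(s^2, v^2, "+"))
  wp <- proj * w
  n_pad <- 2^ceiling(log2(2 * nu))
  if (is.null(H)) H <- ramp_filter_freq(n_pad, ds, window)
  pad <- matrix(0, n_pad, nv)
  pad[seq_len(nu), ] <- wp
  q <- Re(stats::mvfft(stats::mvfft(pad) * H, inverse = TRUE)) / n_pad
  q[seq_len(nu), , drop = FALSE] * ds * 0.5
}

#' Standard FDK reconstruction
#'
#' Feldkamp-Davis-Kress filtered backprojection for a full-arc circular
#' cone-beam scan: cosine weighting, row-wise ramp filtering (zero-padded to
#' the next power of two, Hann-apodised by default), and distance-weighted
#' voxel-driven backprojection with the `2*pi/N_t` angular weight. Voxels
#' outside the FOV cylinder are set to the null value.
#'
#' @param projs a [projection_stack()] of line integrals.
#' @param cfg a [recon_config()].
#' @return a [volume3d()] of attenuation values (per mm).
#' @export
fdk_reconstruct <- function(projs, cfg) {
  acc <- fdk_accumulate(projs, cfg, warp_fun = NULL)
  apply_fov_null(acc, cfg$fov_radius)
}

#' Motion-compensated FDK reconstruction
#'
#' As [fdk_reconstruct()], but each per-projection filtered backprojection
#' volume is resampled into the reference frame before accumulation. The
#' frame-t displacement field `D_t` (pull-back: frame coordinates to
#' reference-sampling offsets) is numerically inverted ([invert_dvf()]) to
#' obtain the reference-to-frame mapping used for the resampling.
#'
#' @param projs a [projection_stack()].
#' @param cfg a [recon_config()].
#' @param model a correspondence model (see [fit_motion_model()]) providing a
#'   control point grid per frame, or `NULL` if `dvf_fun` is given.
#' @param surrogates surrogate matrix `(N_t, N_s)` driving `model`.
#' @param dvf_fun alternative to `model`: `function(t)` returning the frame-t
#'   `dense_dvf` on the reconstruction grid.
#' @return a [volume3d()]: the motion-free estimate.
#' @export
motion_compensated_fdk <- function(projs, cfg, model = NULL, surrogates = NULL,
                                   dvf_fun = NULL) {
  if (is.null(dvf_fun)) {
    if (is.null(model) || is.null(surrogates))
      stop("supply either a model plus surrogates, or dvf_fun")
    surrogates <- as.matrix(surrogates)
    if (nrow(surrogates) != n_frames(projs))
      stop("missing surrogate row for some frame")
    dvf_fun <- function(t)
      ffd_to_dvf(model_cpg_at_time(model, surrogates[t, ]), cfg$grid)
  }
  g <- cfg$grid
  warp_fun <- function(bp, t) {
    d <- dvf_fun(t)
    if (max(abs(d)) == 0) return(bp)
    inv <- invert_dvf(d)
    w <- cpp_warp(bp, g$shape, g$spacing, g$origin, as.numeric(inv),
                  0L, 0, TRUE, FALSE)
    w$value
  }
  acc <- fdk_accumulate(projs, cfg, warp_fun)
  apply_fov_null(acc, cfg$fov_radius)
}

# shared accumulation loop; warp_fun(bp_vector, t) resamples one filtered
# backprojection volume into the reference frame (NULL: standard FDK)
fdk_accumulate <- function(projs, cfg, warp_fun = NULL) {
  stopifnot(inherits(projs, "projection_stack"))
  nt <- n_frames(projs)
  if (nt == 0) stop("empty projection stack")
  geom <- projs$geometry
  g <- cfg$grid
  n_pad <- 2^ceiling(log2(2 * geom$nu))
  ds <- geom$du * geom$sid / geom$sdd
  H <- ramp_filter_freq(n_pad, ds, cfg$filter_window)
  dbeta <- 2 * pi / nt
  acc <- numeric(prod(g$shape))
  for (t in seq_len(nt)) {
    q <- fdk_filter_projection(projs$data[, , t], geom, H, cfg$filter_window)
    bp <- cpp_fdk_backproject_frame(q, g$shape, g$spacing, g$origin,
                                    geom$sid, geom$sdd, geom$nu, geom$nv,
                                    geom$du, geom$dv,
                                    deg2rad(geom$angles[t]))
    if (!is.null(warp_fun)) bp <- warp_fun(bp, t)
    acc <- acc + dbeta * bp
  }
  volume3d(array(acc, g$shape), g$spacing, g$origin)
}
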