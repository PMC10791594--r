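#' Fitting configuration
#'
#' Hyperparameters of the alternating model-fit / motion-compensated
#' reconstruction schedule. The defaults are the conventional choices for
#' projection-domain surrogate-driven fitting: control point spacing of 8
#' voxels, two resolution levels at 1/4 and 1/2 of the original resolution,
#' at most 6 motion-compensated reconstructions per level, at most 100
#' model-fitting iterations (stochastic subset gradient steps) per fit phase,
#' and evenly-spaced subsets each holding one tenth of the projections.
#'
#' @param levels resolution level scale factors, strictly increasing.
#' @param max_mcr_per_level maximum motion-compensated reconstructions per
#'   level.
#' @param max_fit_iters maximum subset gradient steps per fit phase.
#' @param subset_fraction fraction of projections per subset.
#' @param node_spacing_voxels control point spacing in voxels of the level
#'   image.
#' @param lncc a [lncc_config()]; `sigma_px` is interpreted in pixels of the
#'   current level's detector (kept fixed across levels so the window stays
#'   wide relative to any view-aliasing texture in the level image).
#' @param step_scale initial gradient step, as the maximum first-step node
#'   displacement in level-voxel units, before backtracking.
#' @param step_decay_epochs timescale (in epochs over the subsets) of the
#'   `1/(1 + t/tau)` decay of the gradient step within a fit phase.
#' @param level_blur_px Gaussian band-limiting (in level detector pixels)
#'   applied to the measured projections at each resolution level, matching
#'   their bandwidth to the model-side projections of the coarse level image.
#' @param min_rel_improve early-stop threshold on the relative epoch-mean
#'   loss improvement.
#' @param seed seed of the RNG governing the subset visiting order.
#' @param verbose print per-phase progress.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(levels = c(1 / 4, 1 / 2), max_mcr_per_level = 6L,
                       max_fit_iters = 100L, subset_fraction = 1 / 10,
                       node_spacing_voxels = 8, lncc = lncc_config(),
                       step_scale = 0.15, step_decay_epochs = 1,
                       level_blur_px = 0.5, min_rel_improve = 1e-5,
                       seed = 0L, verbose = FALSE) {
  if (!(subset_fraction > 0 && subset_fraction <= 1))
    stop("subset_fraction must be in (0, 1]")
  if (any(diff(levels) <= 0) || any(levels <= 0) || any(levels > 1))
    stop("levels must be strictly increasing scale factors in (0, 1]")
  structure(list(levels = levels, max_mcr_per_level = as.integer(max_mcr_per_level),
                 max_fit_iters = as.integer(max_fit_iters),
                 subset_fraction = subset_fraction,
                 node_spacing_voxels = node_spacing_voxels, lncc = lncc,
                 step_scale = step_scale, step_decay_epochs = step_decay_epochs,
                 level_blur_px = level_blur_px,
                 min_rel_improve = min_rel_improve,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "fit_config")
}

#' Correspondence model container
#'
#' Holds one control-point displacement component per surrogate signal; the
#' frame-t control point grid is the linear combination of the components
#' weighted by the frame's surrogate values.
#'
#' @param template a `control_grid` fixing the node layout.
#' @param n_sig number of surrogate signals.
#' @param components optional list of displacement arrays `(dims, 3)`.
#' @return a list of class `correspondence_model`.
#' @export
correspondence_model <- function(template, n_sig = 2L, components = NULL) {
  if (is.null(components))
    components <- replicate(n_sig, array(0, c(template$dims, 3)), simplify = FALSE)
  stopifnot(length(components) == n_sig)
  for (cc in components) stopifnot(all(dim(cc) == c(template$dims, 3)))
  structure(list(components = components, origin = template$origin,
                 spacing = template$spacing, dims = template$dims,
                 n_sig = as.integer(n_sig)),
            class = "correspondence_model")
}

model_template <- function(model)
  structure(list(disp = array(0, c(model$dims, 3)), origin = model$origin,
                 spacing = model$spacing, dims = model$dims),
            class = "control_grid")

#' @export
print.correspondence_model <- function(x, ...) {
  cat(sprintf("correspondence_model: %d components on %s nodes @ %s mm\n",
              x$n_sig, paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  for (i in seq_len(x$n_sig))
    cat(sprintf("  component %d: max |displacement| %.3g mm\n",
                i, max(abs(x$components[[i]]))))
  invisible(x)
}

#' Control point grid at one time point
#'
#' Evaluates the correspondence model at a surrogate sample: the linear
#' combination `M_t = sum_i S_it C_i` of the model components. Linear in both
#' the components and the surrogate values.
#'
#' @param model a [correspondence_model()].
#' @param surrogate_row numeric vector of length `n_sig`.
#' @return a `control_grid`.
#' @export
model_cpg_at_time <- function(model, surrogate_row) {
  if (length(surrogate_row) != model$n_sig)
    stop("surrogate row length ", length(surrogate_row),
         " does not match the model's ", model$n_sig, " components")
  disp <- array(0, c(model$dims, 3))
  for (i in seq_len(model$n_sig))
    disp <- disp + surrogate_row[i] * model$components[[i]]
  cpg_like(model_template(model), disp)
}

#' Evenly-spaced projection subsets
#'
#' Returns the 1-based indices of the evenly-spaced subset starting at
#' 0-based `offset`: frames `offset, offset + k, offset + 2k, ...` with
#' `k = round(1/fraction)`. The `k` offsets `0..k-1` partition all frames.
#'
#' @param n_t total number of projections.
#' @param fraction subset fraction (e.g. 1/10).
#' @param offset 0-based subset offset in `0..k-1`.
#' @return integer vector of frame indices.
#' @export
subset_indices <- function(n_t, fraction, offset = 0L) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  k <- max(1L, as.integer(round(1 / fraction)))
  offset <- as.integer(offset)
  if (offset < 0 || offset >= k) stop("offset must be in 0..", k - 1L)
  seq.int(offset + 1L, n_t, by = k)
}

# precomputed per-level context for the loss
fit_context <- function(projs, grid, cfg_lncc, fov_radius = NULL) {
  g <- vol_grid(grid)
  geom <- projs$geometry
  if (is.null(fov_radius)) fov_radius <- default_fov_radius(g)
  nt <- n_frames(projs)
  masks <- vector("list", nt)
  for (t in seq_len(nt))
    masks[[t]] <- detector_validity_mask(geom, t, g, fov_radius)
  list(projs = projs, geom = geom, grid = g, masks = masks,
       lncc = cfg_lncc, step = min(g$spacing) / 2)
}

# loss and gradient over a subset, given prefiltered I0 spline coefficients
loss_grad_core <- function(model, i0_coef, ctx, S, subset, want_grad = TRUE) {
  g <- ctx$grid
  geom <- ctx$geom
  loss <- 0
  grad <- NULL
  if (want_grad)
    grad <- replicate(model$n_sig, numeric(prod(model$dims) * 3), simplify = FALSE)
  for (t in subset) {
    cpgt <- model_cpg_at_time(model, S[t, ])
    d <- cpp_ffd_to_dvf(as.numeric(cpgt$disp), cpgt$dims, cpgt$origin,
                        cpgt$spacing, g$shape, g$spacing, g$origin)
    w <- cpp_warp(i0_coef, g$shape, g$spacing, g$origin, d, 1L, 0,
                  FALSE, want_grad)
    pt_est <- cpp_forward_project(w$value, g$shape, g$spacing, g$origin,
                                  geom$sid, geom$sdd, geom$nu, geom$nv,
                                  geom$du, geom$dv,
                                  deg2rad(geom$angles[t]), ctx$step)
    pt <- ctx$projs$data[, , t]
    msk <- ctx$masks[[t]]
    loss <- loss - lncc(pt, pt_est, ctx$lncc, msk)
    if (!want_grad) next
    gl <- lncc_gradient(pt, pt_est, ctx$lncc, msk)
    b <- cpp_back_project(-gl, g$shape, g$spacing, g$origin,
                          geom$sid, geom$sdd, geom$nu, geom$nv,
                          geom$du, geom$dv, deg2rad(geom$angles[t]), ctx$step)
    V <- c(b * w$gx, b * w$gy, b * w$gz)
    cg <- cpp_ffd_adjoint(V, g$shape, g$spacing, g$origin,
                          model$dims, model$origin, model$spacing)
    for (i in seq_len(model$n_sig))
      grad[[i]] <- grad[[i]] + S[t, i] * cg
  }
  list(loss = loss, grad = grad)
}

#' Projection-domain loss and its gradient
#'
#' Evaluates the negative sum, over a subset of frames, of the LNCC between
#' the measured projections and the forward-projected warped reference image,
#' and (optionally) its analytic gradient with respect to the correspondence
#' model components. The gradient is assembled by the chain
#' LNCC-gradient -> adjoint backprojection -> intensity gradient at warped
#' positions -> FFD adjoint -> surrogate weighting.
#'
#' @param model a [correspondence_model()].
#' @param i0 reference image ([volume3d()]); null voxels contribute zero.
#' @param projs a [projection_stack()].
#' @param surrogates `N_t x N_s` surrogate matrix.
#' @param subset integer frame indices (see [subset_indices()]).
#' @param cfg a [fit_config()] (its `lncc` settings are used).
#' @return list with `loss` (scalar) and `gradient` (a
#'   [correspondence_model()]-shaped list of arrays).
#' @export
loss_and_gradient <- function(model, i0, projs, surrogates, subset,
                              cfg = fit_config()) {
  if (length(subset) == 0) stop("empty subset")
  S <- as.matrix(surrogates)
  if (nrow(S) < max(subset)) stop("missing surrogate rows for the subset")
  g <- vol_grid(i0)
  img <- as.numeric(i0)
  img[!is.finite(img)] <- 0
  coef <- cpp_bspline_prefilter(img, g$shape)
  ctx <- fit_context(projs, g, cfg$lncc)
  out <- loss_grad_core(model, coef, ctx, S, subset, want_grad = TRUE)
  list(loss = out$loss,
       gradient = lapply(out$grad, function(v) array(v, c(model$dims, 3))))
}

#' Fit a surrogate-driven respiratory motion model to unsorted projections
#'
#' Jointly estimates a motion-free reference image and a correspondence model
#' mapping two surrogate signals to per-frame B-spline deformations, directly
#' from the 2D projections of a cone-beam scan. Per resolution level the
#' projections are pooled to the level resolution, the reference image is
#' initialised by standard FDK (first level only), and model fitting
#' (stochastic subset gradient descent on the projection-domain LNCC loss)
#' alternates with motion-compensated FDK reconstruction of the reference
#' image. The fitted model advances to the next level by exact B-spline
#' subdivision of its components.
#'
#' @param projs a [projection_stack()] of line integrals.
#' @param surrogates `N_t x 2` surrogate matrix (see [surrogate_matrix()] or
#'   [extract_surrogates()]); columns are normalized to mean 0, sd 1 if they
#'   are not already.
#' @param cfg a [fit_config()].
#' @param grid full-resolution reconstruction grid (`grid3d`); its shape must
#'   be divisible by the inverse level factors.
#' @return An object of class `moco_model`: the fitted components, the final
#'   motion-compensated reference image `i0` (finest fitting level), the fit
#'   log, and the inputs needed by the methods ([predict.moco_model()],
#'   [residuals.moco_model()], [simulate.moco_model()], ...).
#' @export
fit_motion_model <- function(projs, surrogates, cfg = fit_config(), grid) {
  stopifnot(inherits(projs, "projection_stack"))
  grid <- vol_grid(grid)
  nt <- n_frames(projs)
  S <- as.matrix(surrogates)
  if (nrow(S) != nt) stop("surrogate matrix must have one row per projection")
  if (!is_normalized(S)) {
    message("normalizing surrogate columns to mean 0, sd 1")
    S <- apply(S, 2, function(v) (v - mean(v)) / sd(v))
  }
  k <- max(1L, as.integer(round(1 / cfg$subset_fraction)))
  rng <- local_rng(cfg$seed)
  model <- NULL
  i0 <- NULL
  log <- list()
  step_global <- 0L
  for (li in seq_along(cfg$levels)) {
    f <- cfg$levels[li]
    fac <- as.integer(round(1 / f))
    if (any(grid$shape %% fac != 0))
      stop("grid shape must be divisible by 1/level for every level")
    lg <- level_grid(grid, fac)
    lp <- level_projections(projs, fac)
    lpb <- blur_projections(lp, cfg$level_blur_px)
    ctx <- fit_context(lpb, lg, cfg$lncc)
    rc <- recon_config(lg)
    if (is.null(model)) {
      model <- correspondence_model(
        make_control_grid(lg, cfg$node_spacing_voxels * min(lg$spacing)),
        n_sig = ncol(S))
      i0 <- fdk_reconstruct(lp, rc)
    } else {
      comp <- lapply(model$components, function(cc) {
        refine_control_grid(cpg_like(model_template(model), cc))
      })
      tmpl <- comp[[1]]
      model <- correspondence_model(cpg_like(tmpl, array(0, c(tmpl$dims, 3))),
                                    n_sig = ncol(S),
                                    components = lapply(comp, `[[`, "disp"))
      i0 <- motion_compensated_fdk(lp, rc, model, S)
    }
    mu0 <- NULL
    level_iter <- 0L
    for (mcr in seq_len(cfg$max_mcr_per_level)) {
      img <- as.numeric(i0)
      img[!is.finite(img)] <- 0
      coef <- cpp_bspline_prefilter(img, lg$shape)
      offsets <- rng$sample(k) - 1L
      oi <- 0L
      epoch_losses <- c()
      cur_epoch <- c()
      for (iter in seq_len(cfg$max_fit_iters)) {
        oi <- oi + 1L
        if (oi > k) {   # epoch finished: early stop on epoch means
          epoch_losses <- c(epoch_losses, mean(cur_epoch))
          cur_epoch <- c()
          ne <- length(epoch_losses)
          if (ne >= 3) {
            r1 <- rel_improve(epoch_losses[ne - 1], epoch_losses[ne])
            r2 <- rel_improve(epoch_losses[ne - 2], epoch_losses[ne - 1])
            if (r1 < cfg$min_rel_improve && r2 < cfg$min_rel_improve) break
          }
          offsets <- rng$sample(k) - 1L
          oi <- 1L
        }
        sub <- subset_indices(nt_level(lp), cfg$subset_fraction, offsets[oi])
        lgout <- loss_grad_core(model, coef, ctx, S, sub, want_grad = TRUE)
        if (!is.finite(lgout$loss))
          stop("model fit diverged (non-finite loss) at level ", f,
               ", MCR ", mcr, ", iteration ", iter)
        gmax <- max(vapply(lgout$grad, function(v) max(abs(v)), 0))
        if (is.null(mu0))
          mu0 <- init_step_size(model, lgout, coef, ctx, S, sub, cfg, lg)
        mu <- mu0 / (1 + level_iter / (cfg$step_decay_epochs * k))
        level_iter <- level_iter + 1L
        if (gmax > 0 && mu > 0)
          for (i in seq_len(model$n_sig))
            model$components[[i]] <- model$components[[i]] -
              array(mu * lgout$grad[[i]], c(model$dims, 3))
        step_global <- step_global + 1L
        cur_epoch <- c(cur_epoch, lgout$loss)
        log[[length(log) + 1L]] <- data.frame(
          step = step_global, level = f, mcr_iter = mcr, fit_iter = iter,
          subset_offset = offsets[oi], loss = lgout$loss)
      }
      i0 <- motion_compensated_fdk(lp, rc, model, S)
      if (cfg$verbose)
        message(sprintf("level %.3g, MCR %d: loss %.5f", f, mcr,
                        log[[length(log)]]$loss))
    }
  }
  structure(list(components = model$components, origin = model$origin,
                 spacing = model$spacing, dims = model$dims,
                 n_sig = model$n_sig, surrogates = S, geometry = projs$geometry,
                 grid = grid, levels = cfg$levels, i0 = i0,
                 log = do.call(rbind, log), config = cfg,
                 projections = projs, call = match.call()),
            class = c("moco_model", "correspondence_model"))
}

nt_level <- function(projs) n_frames(projs)

# Gaussian band-limiting of measured projections at a resolution level, so
# their bandwidth matches projections of the coarse level image
blur_projections <- function(projs, sigma_px) {
  if (is.null(sigma_px) || sigma_px <= 0) return(projs)
  Ku <- gauss_conv_matrix(dim(projs$data)[1], sigma_px)
  Ku <- Ku / rowSums(Ku)
  Kv <- gauss_conv_matrix(dim(projs$data)[2], sigma_px)
  Kv <- Kv / rowSums(Kv)
  out <- projs
  for (t in seq_len(n_frames(projs)))
    out$data[, , t] <- Ku %*% projs$data[, , t] %*% t(Kv)
  out
}

rel_improve <- function(prev, new) {
  (prev - new) / max(abs(prev), .Machine$double.eps)
}

is_normalized <- function(S, tol_mean = 1e-8, tol_sd = 1e-6) {
  all(abs(colMeans(S)) < tol_mean) && all(abs(apply(S, 2, sd) - 1) < tol_sd)
}

# backtracking search for the per-level constant step size: start with a step
# displacing the largest-gradient node by step_scale level-voxels, halve
# until the subset loss decreases
init_step_size <- function(model, lgout, coef, ctx, S, sub, cfg, lg) {
  gmax <- max(vapply(lgout$grad, function(v) max(abs(v)), 0))
  if (gmax < 1e-12) return(0)
  mu <- cfg$step_scale * min(lg$spacing) / gmax
  for (try in 1:25) {
    trial <- model
    for (i in seq_len(model$n_sig))
      trial$components[[i]] <- trial$components[[i]] -
        array(mu * lgout$grad[[i]], c(model$dims, 3))
    l2 <- loss_grad_core(trial, coef, ctx, S, sub, want_grad = FALSE)$loss
    if (is.finite(l2) && l2 < lgout$loss) return(mu)
    mu <- mu / 2
  }
  mu
}
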