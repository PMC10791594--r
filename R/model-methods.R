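#' @export
print.moco_model <- function(x, ...) {
  cat("Surrogate-driven respiratory motion model\n")
  cat(sprintf("  %d frames, %d surrogate signals; levels %s\n",
              n_frames(x$geometry), x$n_sig,
              paste(signif(x$levels, 3), collapse = ", ")))
  cat(sprintf("  components on %s nodes @ %s mm\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  cat(sprintf("  final subset loss %.5f after %d gradient steps\n",
              x$log$loss[nrow(x$log)], nrow(x$log)))
  invisible(x)
}

#' @export
summary.moco_model <- function(object, ...) {
  dmag <- vapply(seq_len(nrow(object$surrogates)), function(t) {
    cp <- model_cpg_at_time(object, object$surrogates[t, ])
    max(sqrt(rowSums(matrix(cp$disp, ncol = 3)^2)))
  }, 0)
  out <- list(
    n_frames = n_frames(object$geometry),
    n_sig = object$n_sig,
    levels = object$levels,
    node_spacing = object$spacing,
    steps = nrow(object$log),
    mcr_per_level = tapply(object$log$mcr_iter, object$log$level, max),
    loss_first = object$log$loss[1],
    loss_final = object$log$loss[nrow(object$log)],
    max_node_displacement = max(dmag)
  )
  class(out) <- "summary.moco_model"
  out
}

#' @export
print.summary.moco_model <- function(x, ...) {
  cat("Motion model fit summary\n")
  cat(sprintf("  frames: %d, signals: %d\n", x$n_frames, x$n_sig))
  cat(sprintf("  levels: %s; node spacing %s mm\n",
              paste(signif(x$levels, 3), collapse = ", "),
              paste(signif(x$node_spacing, 3), collapse = "x")))
  cat(sprintf("  gradient steps: %d; MCRs per level: %s\n", x$steps,
              paste(x$mcr_per_level, collapse = ", ")))
  cat(sprintf("  subset loss: %.5f -> %.5f\n", x$loss_first, x$loss_final))
  cat(sprintf("  max per-frame node displacement: %.2f mm\n",
              x$max_node_displacement))
  invisible(x)
}

#' @export
coef.moco_model <- function(object, ...) {
  stats::setNames(object$components,
                  colnames(object$surrogates) %||% paste0("C", seq_len(object$n_sig)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-frame deformations from a fitted motion model
#'
#' @param object a fitted `moco_model`.
#' @param newdata surrogate matrix (rows = time points); default the fitted
#'   surrogates.
#' @param grid target grid for dense fields; default the full-resolution
#'   reconstruction grid of the fit.
#' @param frames frame indices to evaluate (default all rows of `newdata`).
#' @param type `"dvf"` for dense fields, `"cpg"` for control point grids.
#' @param ... unused.
#' @return list (one element per frame) of `dense_dvf` or `control_grid`.
#' @export
predict.moco_model <- function(object, newdata = NULL, grid = NULL,
                               frames = NULL, type = c("dvf", "cpg"), ...) {
  type <- match.arg(type)
  S <- if (is.null(newdata)) object$surrogates else as.matrix(newdata)
  if (is.null(frames)) frames <- seq_len(nrow(S))
  if (is.null(grid)) grid <- object$grid
  lapply(frames, function(t) {
    cp <- model_cpg_at_time(object, S[t, ])
    if (type == "cpg") cp else ffd_to_dvf(cp, grid)
  })
}

#' Per-frame similarity residuals of a fitted motion model
#'
#' Recomputes, at the finest fitting level, the LNCC between each measured
#' projection and the forward projection of the warped reference image, and
#' returns `1 - LNCC` per frame (0 = perfect local-affine agreement).
#'
#' @param object a fitted `moco_model`.
#' @param ... unused.
#' @return numeric vector, one residual per frame.
#' @export
residuals.moco_model <- function(object, ...) {
  f <- object$levels[length(object$levels)]
  fac <- as.integer(round(1 / f))
  lg <- level_grid(object$grid, fac)
  lp <- blur_projections(level_projections(object$projections, fac),
                         object$config$level_blur_px)
  ctx <- fit_context(lp, lg, object$config$lncc)
  img <- as.numeric(object$i0)
  img[!is.finite(img)] <- 0
  coef <- cpp_bspline_prefilter(img, lg$shape)
  model <- structure(list(components = object$components, origin = object$origin,
                          spacing = object$spacing, dims = object$dims,
                          n_sig = object$n_sig), class = "correspondence_model")
  vapply(seq_len(n_frames(lp)), function(t) {
    1 + loss_grad_core(model, coef, ctx, object$surrogates, t,
                       want_grad = FALSE)$loss
  }, 0)
}

#' Plot the fit log of a motion model
#'
#' Subset loss per gradient step, coloured by resolution level, with
#' motion-compensated reconstruction boundaries marked.
#'
#' @param x a fitted `moco_model`.
#' @param ... passed to [plot()].
#' @export
plot.moco_model <- function(x, ...) {
  lg <- x$log
  cols <- as.integer(factor(lg$level)) + 1L
  plot(lg$step, lg$loss, col = cols, pch = 16, cex = 0.6,
       xlab = "gradient step", ylab = "subset loss (-sum LNCC)", ...)
  bnd <- which(diff(lg$mcr_iter) != 0 | diff(lg$level) != 0)
  abline(v = lg$step[bnd] + 0.5, col = "grey80", lty = 3)
  legend("topright", legend = paste("level", signif(unique(lg$level), 3)),
         col = sort(unique(cols)), pch = 16, bty = "n")
  invisible(x)
}

#' Animate a fitted motion model
#'
#' Warps the motion-compensated reference image to each requested frame
#' (`simulate` method), producing the estimated dynamic image sequence. With
#' `bins`, frames are grouped into respiratory phase bins and each bin's
#' volume is generated from the bin-average surrogate values (a synthetic
#' phase-sorted 4D sequence).
#'
#' @param object a fitted `moco_model`.
#' @param nsim unused (one sequence is deterministic given the model).
#' @param seed unused.
#' @param frames frame indices (default all).
#' @param i0 reference image; default the fitted `i0`.
#' @param bins number of phase bins, or `NULL` for per-frame output.
#' @param ... unused.
#' @return list of [volume3d()] frames (per frame, or per phase bin).
#' @export
simulate.moco_model <- function(object, nsim = 1, seed = NULL, frames = NULL,
                                i0 = NULL, bins = NULL, ...) {
  animate(object, frames = frames, i0 = i0, bins = bins)
}

#' @rdname simulate.moco_model
#' @param model a fitted `moco_model` (or any `correspondence_model` if `i0`
#'   and `surrogates` are supplied).
#' @param surrogates surrogate matrix; default the fitted one.
#' @export
animate <- function(model, frames = NULL, i0 = NULL, surrogates = NULL,
                    bins = NULL) {
  S <- if (is.null(surrogates)) model$surrogates else as.matrix(surrogates)
  if (is.null(i0)) i0 <- model$i0
  g <- vol_grid(i0)
  if (is.null(frames)) frames <- seq_len(nrow(S))
  if (max(frames) > nrow(S)) stop("missing surrogate rows for requested frames")
  if (!is.null(bins)) {
    ph <- S[frames, 1]
    cut_ <- cut(ph, breaks = stats::quantile(ph, probs = seq(0, 1, length.out = bins + 1)),
                include.lowest = TRUE)
    S <- do.call(rbind, lapply(levels(cut_), function(lv)
      colMeans(S[frames[cut_ == lv], , drop = FALSE])))
    frames <- seq_len(nrow(S))
  }
  lapply(frames, function(t) {
    d <- ffd_to_dvf(model_cpg_at_time(model, S[t, ]), g)
    warp_image(i0, d, interp = "linear")
  })
}
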