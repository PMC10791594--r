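#' Compare uncorrected, truth-signal and extracted-signal scenarios
#'
#' Evaluates the full metric panel on a simulated case for up to three
#' scenarios: `S_uncorr` (no motion compensation: zero fields, static tumor
#' mask, standard FDK), `S_truth_signals` (model fitted with the generating
#' breathing traces), and `S_IA` (model fitted with the intensity-analysis
#' signal and its temporal gradient). Image metrics compare each scenario's
#' reconstruction against the motion-compensated reconstruction using the
#' ground-truth fields. Also emits per-frame tumor centroid displacement
#' series (superior-inferior and anterior-posterior) and their Pearson
#' correlation with the ground truth.
#'
#' @param sim a [simulate_case()] result.
#' @param models named list of fitted `moco_model`s: any of `truth`
#'   (-> `S_truth_signals`) and `ia` (-> `S_IA`); may be empty.
#' @param grid evaluation/reconstruction grid; default the simulation grid.
#' @return a list of class `scenario_report`: per-scenario metrics
#'   (`e_d`, `dsc`, `e_center`, `nrmse`, `ssim`), centroid series, and the
#'   VOI size.
#' @export
run_scenarios <- function(sim, models = list(), grid = NULL) {
  stopifnot(inherits(sim, "moco_sim"))
  if (is.null(grid)) grid <- vol_grid(sim$phantom)
  grid <- vol_grid(grid)
  nt <- n_frames(sim$geometry)
  rc <- recon_config(grid)
  fov <- fov_mask(grid, rc$fov_radius)
  body <- array(sim$phantom > min(sim$spec$mu[sim$spec$mu > 0]) / 2, grid$shape)
  voi <- body & fov
  ref_mask <- sim$tumor_mask
  ref_cent <- mask_centroid(ref_mask)

  gt_dvf <- function(t) sim$motion$dvf_fun(t, grid)
  gt_masks <- lapply(seq_len(nt), function(t) warp_mask(ref_mask, gt_dvf(t)))
  i0_gt <- motion_compensated_fdk(sim$projections, rc, dvf_fun = gt_dvf)

  scen_defs <- list(S_uncorr = NULL)
  if (!is.null(models$truth)) scen_defs$S_truth_signals <- models$truth
  if (!is.null(models$ia)) scen_defs$S_IA <- models$ia

  gt_series <- centroid_series(gt_masks, ref_cent)
  out <- lapply(names(scen_defs), function(nm) {
    model <- scen_defs[[nm]]
    if (is.null(model)) {
      est_dvf <- function(t) zero_dvf(grid)
      est_masks <- replicate(nt, ref_mask, simplify = FALSE)
      recon <- fdk_reconstruct(sim$projections, rc)
    } else {
      est_dvf <- function(t)
        ffd_to_dvf(model_cpg_at_time(model, model$surrogates[t, ]), grid)
      est_masks <- lapply(seq_len(nt), function(t) warp_mask(ref_mask, est_dvf(t)))
      recon <- motion_compensated_fdk(sim$projections, rc, model, model$surrogates)
    }
    # streaming E_D to avoid holding all fields
    e_d <- mean(vapply(seq_len(nt), function(t) {
      d <- est_dvf(t) - gt_dvf(t)
      mag <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
      mean(mag[voi])
    }, 0))
    series <- centroid_series(est_masks, ref_cent)
    r_si <- series_cor(series$si, gt_series$si)
    r_ap <- series_cor(series$ap, gt_series$ap)
    list(scenario = nm,
         e_d = e_d,
         dsc = dice_coefficient(est_masks, gt_masks),
         e_center = centroid_error(est_masks, gt_masks),
         nrmse = nrmse(recon, i0_gt, voi),
         ssim = ssim_volume(recon, i0_gt, voi),
         r_si = r_si, r_ap = r_ap,
         series = data.frame(frame = seq_len(nt),
                             est_si = series$si, est_ap = series$ap,
                             gt_si = gt_series$si, gt_ap = gt_series$ap))
  })
  names(out) <- names(scen_defs)
  structure(list(scenarios = out, voi_voxels = sum(voi),
                 n_frames = nt, grid = grid),
            class = "scenario_report")
}

centroid_series <- function(masks, ref_cent) {
  cents <- t(vapply(masks, mask_centroid, numeric(3)))
  list(si = cents[, 3] - ref_cent[3], ap = cents[, 2] - ref_cent[2])
}

series_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Scenario comparison (", x$n_frames, " frames, VOI ",
      x$voi_voxels, " voxels)\n", sep = "")
  df <- summary(x)
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.scenario_report <- function(object, ...) {
  do.call(rbind, lapply(object$scenarios, function(s)
    data.frame(scenario = s$scenario, e_d = s$e_d, dsc = s$dsc,
               e_center = s$e_center, nrmse = s$nrmse, ssim = s$ssim,
               r_si = s$r_si, r_ap = s$r_ap)))
}

#' Write/read a scenario report
#'
#' JSON serialization round-tripping all metrics and per-frame series.
#'
#' @param report a `scenario_report`.
#' @param path file path.
#' @return `read_report` returns a `scenario_report`.
#' @export
write_report <- function(report, path) {
  obj <- list(voi_voxels = report$voi_voxels, n_frames = report$n_frames,
              grid = unclass(report$grid),
              scenarios = lapply(report$scenarios, function(s) {
                s$series <- as.list(s$series)
                s
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scen <- lapply(seq_len(nrow_or_len(obj$scenarios)), function(i) {
    s <- if (is.data.frame(obj$scenarios)) as.list(obj$scenarios[i, ]) else obj$scenarios[[i]]
    s$series <- as.data.frame(s$series)
    s
  })
  names(scen) <- vapply(scen, function(s) s$scenario, "")
  structure(list(scenarios = scen, voi_voxels = obj$voi_voxels,
                 n_frames = obj$n_frames,
                 grid = grid3d(obj$grid$shape, obj$grid$spacing, obj$grid$origin)),
            class = "scenario_report")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
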