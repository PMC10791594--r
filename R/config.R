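#' Assemble a run configuration
#'
#' Nested configuration used by the command-line tools: geometry, phantom,
#' fitting, similarity, surrogate-extraction and reconstruction settings plus
#' the global seed. Unknown keys are rejected; the defaults reproduce the
#' standard hyperparameters (node spacing 8 voxels, levels 1/4 and 1/2, at
#' most 6 motion-compensated reconstructions and 100 fit iterations per
#' level, 1/10 subsets).
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   `fit = list(max_fit_iters = 50)`).
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 0L,
    geometry = list(n_proj = 310L, sid = 1000, sdd = 1536,
                    detector_px = c(128L, 128L), detector_spacing = c(3.2, 3.2),
                    arc = 360, fps = 5.4),
    phantom = list(shape = 128L, spacing = 2, tumor_radius = 15,
                   regime = "regular"),
    fit = list(levels = c(1 / 4, 1 / 2), max_mcr_per_level = 6L,
               max_fit_iters = 100L, subset_fraction = 1 / 10,
               node_spacing_voxels = 8, step_scale = 0.15,
               step_decay_epochs = 1, level_blur_px = 0.5,
               min_rel_improve = 1e-5),
    lncc = list(sigma_px = 5, variance_floor = 1e-8),
    surrogate = list(band_split_hz = 0.1),
    reconstruction = list(shape = 128L, spacing = 2, filter_window = "hann")
  )
  cfg <- merge_config(defaults, list(...), path = "")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, override, path) {
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]])) stop("configuration key ", key, " must be a list")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys validated against [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  do.call(run_config, yaml::read_yaml(path))
}

#' @export
print.run_config <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

fit_config_from_run <- function(cfg) {
  fit_config(levels = cfg$fit$levels,
             max_mcr_per_level = cfg$fit$max_mcr_per_level,
             max_fit_iters = cfg$fit$max_fit_iters,
             subset_fraction = cfg$fit$subset_fraction,
             node_spacing_voxels = cfg$fit$node_spacing_voxels,
             lncc = lncc_config(cfg$lncc$sigma_px, cfg$lncc$variance_floor),
             step_scale = cfg$fit$step_scale,
             step_decay_epochs = cfg$fit$step_decay_epochs,
             level_blur_px = cfg$fit$level_blur_px,
             min_rel_improve = cfg$fit$min_rel_improve,
             seed = cfg$seed)
}
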