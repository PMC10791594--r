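# Shared fixtures, built lazily and memoised for the session.
# The "study" fixtures reproduce the package's desk-scale validation
# conditions: 64^3 thorax phantom at 4 mm, 60 projections uniformly spanning
# a one-minute 360-degree rotation (a subsampled standard protocol, as in
# public challenge datasets), 256^2 detector at 1.8 mm, regular breathing
# with 30/7 mm trace amplitudes.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

study_geometry <- function(n_proj = 60L)
  cbct_geometry(n_proj = n_proj, detector_px = c(256L, 256L),
                detector_spacing = c(1.8, 1.8), fps = n_proj / 57.4)

study_spec <- function() phantom_spec(grid = grid3d(64L, 4))

study_sim <- function() memo_fixture("study_sim", function() {
  simulate_case("regular", study_spec(), study_geometry(), seed = 1)
})

study_fit_truth <- function() memo_fixture("study_fit_truth", function() {
  sim <- study_sim()
  fit_motion_model(sim$projections, sim$motion$S, fit_config(),
                   vol_grid(sim$phantom))
})

study_fit_ia <- function() memo_fixture("study_fit_ia", function() {
  sim <- study_sim()
  S <- extract_surrogates(sim$projections)
  fit_motion_model(sim$projections, S, fit_config(), vol_grid(sim$phantom))
})

study_report <- function() memo_fixture("study_report", function() {
  run_scenarios(study_sim(),
                models = list(truth = study_fit_truth(), ia = study_fit_ia()))
})

# small smooth test volume with hard compact support (exactly zero near the
# boundary, so edge interpolation effects cannot leak into loss comparisons)
blob_volume <- function(n = 16L, spacing = 4) {
  g <- grid3d(n, spacing)
  x <- axis_coords(g, 1); y <- axis_coords(g, 2); z <- axis_coords(g, 3)
  b <- function(cx, cy, cz, s)
    outer(outer(exp(-(x - cx)^2 / (2 * s^2)), exp(-(y - cy)^2 / (2 * s^2))),
          exp(-(z - cz)^2 / (2 * s^2)))
  ext <- (n - 1) * spacing / 2
  v <- 0.02 * b(0.12 * ext, -0.1 * ext, 0.08 * ext, 0.11 * n * spacing) +
       0.015 * b(-0.2 * ext, 0.15 * ext, -0.12 * ext, 0.09 * n * spacing)
  v[v < 2e-3 * max(v)] <- 0
  volume3d(v, spacing)
}

# a tiny fitted model for exercising the S3 methods cheaply
tiny_fit <- function() memo_fixture("tiny_fit", function() {
  geom <- cbct_geometry(n_proj = 12L, detector_px = c(48L, 48L),
                        detector_spacing = c(9.6, 9.6))
  spec <- phantom_spec(grid = grid3d(24L, 32 / 3))
  sim <- simulate_case("regular", spec, geom, seed = 3)
  cfg <- fit_config(max_fit_iters = 6L, max_mcr_per_level = 2L,
                    subset_fraction = 1 / 4)
  list(sim = sim,
       fit = fit_motion_model(sim$projections, sim$motion$S, cfg,
                              vol_grid(sim$phantom)))
})
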