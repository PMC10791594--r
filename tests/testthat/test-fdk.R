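static_sphere_stack <- function() {
  memo_fixture("fdk_sphere", function() {
    g <- grid3d(48L, 3)
    geom <- cbct_geometry(n_proj = 120L, detector_px = c(64L, 64L),
                          detector_spacing = c(6.4, 6.4))
    cc <- axis_coords(g, 1)
    r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
    vol <- volume3d(array(0.02 * (r2 <= 30^2), g$shape), g$spacing)
    arr <- array(0, c(64, 64, 120))
    for (t in 1:120) arr[, , t] <- forward_project(vol, geom, t)
    list(grid = g, projs = projection_stack(arr, geom), r2 = r2)
  })
}

test_that("FDK recovers the attenuation of an analytic sphere", {
  fx <- static_sphere_stack()
  rec <- fdk_reconstruct(fx$projs, recon_config(fx$grid))
  eroded <- fx$r2 <= 24^2
  expect_equal(mean(rec[eroded]), 0.02, tolerance = 0.1)
  mid <- rec[, , 24]
  cc <- axis_coords(fx$grid, 1)
  mid_er <- outer(cc^2, cc^2, "+") <= 24^2
  expect_equal(mean(mid[mid_er]), 0.02, tolerance = 0.1)
  # out-of-FOV voxels carry the null value
  expect_true(all(is.na(rec[!fov_mask(fx$grid)])))
})

test_that("FDK is linear and rejects degenerate input", {
  fx <- static_sphere_stack()
  cfg <- recon_config(fx$grid)
  sub <- projection_stack(fx$projs$data[, , 1:20, drop = FALSE],
                          cbct_geometry(n_proj = 20L, detector_px = c(64L, 64L),
                                        detector_spacing = c(6.4, 6.4),
                                        angles = fx$projs$geometry$angles[1:20],
                                        times = fx$projs$geometry$times[1:20]))
  r1 <- fdk_reconstruct(sub, cfg)
  sub3 <- sub; sub3$data <- 3 * sub3$data
  r3 <- fdk_reconstruct(sub3, cfg)
  expect_equal(unclass(r3), 3 * unclass(r1), tolerance = 1e-12)
  zs <- sub; zs$data[] <- 0
  rz <- fdk_reconstruct(zs, cfg)
  expect_true(all(is.na(rz) | rz == 0))
})

test_that("motion-compensated FDK with identity motion equals FDK", {
  fx <- static_sphere_stack()
  cfg <- recon_config(fx$grid)
  rec <- fdk_reconstruct(fx$projs, cfg)
  mc <- motion_compensated_fdk(fx$projs, cfg,
                               dvf_fun = function(t) zero_dvf(fx$grid))
  reldiff <- max(abs(mc - rec), na.rm = TRUE) / max(abs(rec), na.rm = TRUE)
  expect_lt(reldiff, 1e-6)
})

test_that("single-frame MC-FDK equals the warped single-frame FDK", {
  fx <- static_sphere_stack()
  g1 <- cbct_geometry(n_proj = 1L, detector_px = c(64L, 64L),
                      detector_spacing = c(6.4, 6.4),
                      angles = fx$projs$geometry$angles[5], times = 0)
  one <- projection_stack(fx$projs$data[, , 5, drop = FALSE], g1)
  cfg <- recon_config(fx$grid)
  d <- zero_dvf(fx$grid)
  d[, , , 3] <- 6  # constant 2-voxel shift: trivially invertible
  dvf <- dense_dvf(unclass(d), attr(d, "spacing"), attr(d, "origin"))
  mc <- motion_compensated_fdk(one, cfg, dvf_fun = function(t) dvf)
  fb <- fdk_reconstruct(one, cfg)
  inv <- invert_dvf(dvf)
  manual <- warp_image(volume3d(ifelse(is.na(fb), 0, unclass(fb)),
                                attr(fb, "spacing"), attr(fb, "origin")),
                       inv, interp = "linear", fill = 0)
  ok <- !is.na(mc) & !is.na(manual)
  # interior agreement (edge-clamp vs zero-fill differ at the boundary)
  core <- array(FALSE, fx$grid$shape); core[8:41, 8:41, 8:41] <- TRUE
  expect_equal(unclass(mc)[ok & core], unclass(manual)[ok & core],
               tolerance = 1e-10)
})

test_that("MC-FDK with ground-truth motion beats plain FDK on a moving sphere", {
  g <- grid3d(32L, 4)
  geom <- cbct_geometry(n_proj = 40L, detector_px = c(64L, 64L),
                        detector_spacing = c(6.4, 6.4))
  cc <- axis_coords(g, 1)
  sph <- function(dz) {
    r2 <- outer(outer(cc^2, cc^2, "+"), (cc - dz)^2, "+")
    volume3d(array(0.02 * (r2 <= 24^2), g$shape), g$spacing)
  }
  # oscillating SI translation, +/- 8 mm
  dz <- 8 * sin(2 * pi * (0:39) / 10)
  arr <- array(0, c(64, 64, 40))
  for (t in 1:40) arr[, , t] <- forward_project(sph(dz[t]), geom, t)
  projs <- projection_stack(arr, geom)
  cfg <- recon_config(g)
  dvf_t <- function(t) {
    d <- zero_dvf(g); d[, , , 3] <- -dz[t]  # pull-back: I_t(x) = I0(x + D)
    dense_dvf(unclass(d), attr(d, "spacing"), attr(d, "origin"))
  }
  static_arr <- array(0, c(64, 64, 40))
  for (t in 1:40) static_arr[, , t] <- forward_project(sph(0), geom, t)
  oracle <- fdk_reconstruct(projection_stack(static_arr, geom), cfg)
  mc <- motion_compensated_fdk(projs, cfg, dvf_fun = dvf_t)
  fdk <- fdk_reconstruct(projs, cfg)
  voi <- !is.na(oracle)
  err_mc <- nrmse(mc, oracle, voi)
  err_fdk <- nrmse(fdk, oracle, voi)
  expect_lt(err_mc, err_fdk)
  # motion compensation restores the edge: max SI gradient across the sphere
  grad_mag <- function(v) max(abs(diff(ifelse(is.na(unclass(v)), 0, unclass(v))[17, 17, ])))
  expect_gt(grad_mag(mc), grad_mag(fdk))
})

test_that("MC-FDK validates its inputs", {
  fx <- static_sphere_stack()
  cfg <- recon_config(fx$grid)
  expect_error(motion_compensated_fdk(fx$projs, cfg), "supply either")
  tmpl <- make_control_grid(fx$grid, 48)
  model <- correspondence_model(tmpl, 2)
  expect_error(motion_compensated_fdk(fx$projs, cfg, model,
                                      matrix(0, 10, 2)),
               "missing surrogate row")
})
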