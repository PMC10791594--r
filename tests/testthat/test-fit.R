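test_that("model evaluation at a time point is bilinear", {
  set.seed(16)
  tmpl <- make_control_grid(grid3d(12L, 4), 16)
  model <- correspondence_model(tmpl, 2)
  expect_equal(max(abs(model_cpg_at_time(model, c(0.7, -1.2))$disp)), 0)
  c1 <- array(rnorm(prod(tmpl$dims) * 3), c(tmpl$dims, 3))
  c2 <- array(rnorm(prod(tmpl$dims) * 3), c(tmpl$dims, 3))
  model <- correspondence_model(tmpl, 2, components = list(c1, c2))
  expect_equal(model_cpg_at_time(model, c(1, 0))$disp, c1)
  expect_equal(model_cpg_at_time(model, c(0, 1))$disp, c2)
  s1 <- c(0.3, -0.8); s2 <- c(-1.1, 0.4); a <- 2; b <- -0.5
  expect_equal(model_cpg_at_time(model, a * s1 + b * s2)$disp,
               a * model_cpg_at_time(model, s1)$disp +
               b * model_cpg_at_time(model, s2)$disp, tolerance = 1e-12)
  expect_error(model_cpg_at_time(model, c(1, 2, 3)), "does not match")
})

test_that("evenly-spaced subsets partition the frames", {
  idx <- subset_indices(310, 1 / 10, 0)
  expect_equal(idx, seq(1L, 301L, by = 10L))
  expect_length(idx, 31L)
  all_idx <- sort(unlist(lapply(0:9, function(o) subset_indices(310, 1 / 10, o))))
  expect_equal(all_idx, 1:310)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_equal(subset_indices(17, 1, 0), 1:17)
  expect_error(subset_indices(310, 0), "fraction")
  expect_error(subset_indices(310, 1 / 10, 10), "offset")
})

test_that("loss is at its global optimum for a static scan with perfect I0", {
  vol <- blob_volume(16L, 4)
  g <- vol_grid(vol)
  geom <- cbct_geometry(n_proj = 6L, detector_px = c(24L, 24L),
                        detector_spacing = c(5, 5))
  arr <- array(0, c(24, 24, 6))
  for (t in 1:6) arr[, , t] <- forward_project(vol, geom, t)
  projs <- projection_stack(arr, geom)
  S <- matrix(rnorm(12), 6, 2)
  model <- correspondence_model(make_control_grid(g, 32), 2)
  lg <- loss_and_gradient(model, vol, projs, S, 1:4, fit_config())
  expect_equal(lg$loss, -4, tolerance = 1e-6)
  expect_lt(max(abs(unlist(lg$gradient))), 1e-5)
})

test_that("loss gradient matches finite differences on a small instance", {
  set.seed(17)
  vol <- blob_volume(12L, 4)
  g <- vol_grid(vol)
  geom <- cbct_geometry(n_proj = 2L, detector_px = c(16L, 16L),
                        detector_spacing = c(7, 7))
  S <- matrix(rnorm(4), 2, 2)
  tmpl <- make_control_grid(g, 24)
  truth <- correspondence_model(tmpl, 2, components = list(
    array(rnorm(prod(tmpl$dims) * 3), c(tmpl$dims, 3)),
    array(rnorm(prod(tmpl$dims) * 3), c(tmpl$dims, 3))))
  arr <- array(0, c(16, 16, 2))
  for (t in 1:2) {
    d <- ffd_to_dvf(model_cpg_at_time(truth, S[t, ]), g)
    arr[, , t] <- forward_project(warp_image(vol, d, fill = 0), geom, t)
  }
  projs <- projection_stack(arr, geom)
  model <- correspondence_model(tmpl, 2)
  cfg <- fit_config()
  lg <- loss_and_gradient(model, vol, projs, S, 1:2, cfg)
  lossfun <- function(m) loss_and_gradient(m, vol, projs, S, 1:2, cfg)$loss
  gmax <- max(abs(unlist(lg$gradient)))
  h <- 1e-3
  set.seed(18)
  ent <- sample(prod(tmpl$dims) * 3, 8)
  for (i in 1:2) for (e in ent[1:4]) {
    mp <- model; mp$components[[i]][e] <- h
    mm <- model; mm$components[[i]][e] <- -h
    fd <- (lossfun(mp) - lossfun(mm)) / (2 * h)
    expect_lt(abs(lg$gradient[[i]][e] - fd) / max(abs(fd), 1e-3 * gmax), 1e-3)
  }
})

test_that("doubling a surrogate column doubles that component's gradient", {
  set.seed(19)
  vol <- blob_volume(12L, 4)
  g <- vol_grid(vol)
  geom <- cbct_geometry(n_proj = 3L, detector_px = c(16L, 16L),
                        detector_spacing = c(7, 7))
  arr <- array(0, c(16, 16, 3))
  for (t in 1:3) arr[, , t] <- forward_project(vol, geom, t) + 0.05
  # make measured differ from estimated so the LNCC gradient is nonzero
  arr <- arr * 1.1 + array(rnorm(length(arr), sd = 0.02), dim(arr))
  projs <- projection_stack(arr, geom)
  S <- matrix(rnorm(6), 3, 2)
  model <- correspondence_model(make_control_grid(g, 24), 2)
  cfg <- fit_config()
  g1 <- loss_and_gradient(model, vol, projs, S, 1:3, cfg)$gradient
  S2 <- S; S2[, 2] <- 2 * S2[, 2]
  g2 <- loss_and_gradient(model, vol, projs, S2, 1:3, cfg)$gradient
  expect_equal(g2[[2]], 2 * g1[[2]], tolerance = 1e-10)
  expect_equal(g2[[1]], g1[[1]], tolerance = 1e-10)
})

test_that("the fit runs its multi-resolution schedule and returns a model", {
  fx <- tiny_fit()
  fit <- fx$fit
  expect_s3_class(fit, "moco_model")
  lg <- fit$log
  expect_setequal(unique(lg$level), c(1 / 4, 1 / 2))
  expect_lte(max(lg$mcr_iter), 2)
  expect_lte(max(lg$fit_iter), 6)
  expect_true(all(lg$subset_offset %in% 0:3))
  expect_true(all(is.finite(lg$loss)))
  expect_s3_class(fit$i0, "volume3d")
  expect_equal(dim(fit$i0)[1], 12L)  # finest level of a 24-voxel grid
})

test_that("surrogates are normalized on entry when needed", {
  fx <- tiny_fit()
  raw <- cbind(fx$sim$traces$s_diaphragm$values, fx$sim$traces$s_chest$values)
  expect_message(
    fit_motion_model(fx$sim$projections, 5 * raw + 2,
                     fit_config(levels = 1 / 2, max_fit_iters = 2L,
                                max_mcr_per_level = 1L, subset_fraction = 1 / 3),
                     vol_grid(fx$sim$phantom)),
    "normalizing")
})
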