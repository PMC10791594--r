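test_that("reference phantom: tumor volume, attenuation bounds, full-scale grid", {
  spec <- phantom_spec(grid = grid3d(64L, 4))
  ref <- make_reference_phantom(spec)
  vox <- prod(vol_grid(ref$volume)$spacing)
  analytic <- 4 / 3 * pi * 15^3
  expect_equal(sum(ref$tumor_mask) * vox, analytic, tolerance = 0.05 * analytic)
  expect_true(all(ref$volume >= 0))
  expect_true(all(ref$volume <= 0.05))
  # tumor voxels sit inside a lung-attenuation neighbourhood
  expect_true(all(ref$volume[ref$tumor_mask == 1] == spec$mu[["tumor"]]))

  full <- phantom_spec(full_scale = TRUE)
  expect_equal(full$grid$shape, c(375L, 375L, 343L))
  expect_equal(full$grid$spacing, c(1, 1, 1))

  expect_error(phantom_spec(tumor_center = c(0, 0, 0)), "inside a lung")
})

test_that("breathing traces: regimes, duration, correlation structure", {
  tr <- make_breathing_traces("regular", n_t = 310L)
  expect_equal(diff(range(tr$s_diaphragm$times)), 309 / 5.4, tolerance = 1e-9)
  expect_gt(cor(tr$s_diaphragm$values, tr$s_chest$values), 0.99)
  expect_equal(tr$phase_offset_deg, 0)
  expect_equal(tr$variability, 0)

  ir <- make_breathing_traces("irregular", n_t = 324L, seed = 4)  # whole cycles
  expect_lt(abs(cor(ir$s_diaphragm$values, ir$s_chest$values)), 0.3)
  # per-cycle amplitude variability is present
  cyc_max <- tapply(ir$s_diaphragm$values,
                    floor((seq_len(324) - 1) / (5.4 * 4)), max)
  expect_gt(sd(cyc_max) / mean(cyc_max), 0.05)
  # seeded reproducibility
  ir2 <- make_breathing_traces("irregular", n_t = 324L, seed = 4)
  expect_identical(ir$s_diaphragm$values, ir2$s_diaphragm$values)
})

test_that("ground-truth motion: zero-signal frames, Jacobians, tumor linearity", {
  spec <- phantom_spec(grid = grid3d(32L, 8))
  traces <- make_breathing_traces("regular", n_t = 40L)
  motion <- make_gt_motion(traces, spec)
  g <- spec$grid

  # frame where both normalized signals are ~0 has ~no displacement
  s2 <- rowSums(motion$S^2)
  t0 <- which.min(s2)
  d0 <- motion$dvf_fun(t0, g)
  expect_lt(max(abs(d0)), 0.5 + 40 * sqrt(s2[t0]))

  # numeric Jacobian determinant stays positive at the extreme frame
  text <- which.max(abs(motion$S[, 1]))
  d <- motion$dvf_fun(text, g)
  jac_min <- local({
    sp <- g$spacing
    # det(I + grad D) via central differences
    gr <- array(0, c(g$shape - 2L, 3, 3))
    for (cmp in 1:3) for (ax in 1:3) {
      idx0 <- lapply(g$shape, function(n) 2:(n - 1))
      idxp <- idx0; idxp[[ax]] <- idxp[[ax]] + 1L
      idxm <- idx0; idxm[[ax]] <- idxm[[ax]] - 1L
      gr[, , , cmp, ax] <- (do.call(`[`, c(list(unclass(d)), idxp, list(cmp))) -
                            do.call(`[`, c(list(unclass(d)), idxm, list(cmp)))) /
        (2 * sp[ax])
    }
    dets <- gr[, , , 1, 1]
    dmin <- Inf
    dims <- dim(gr)[1:3]
    J <- array(0, c(3, 3))
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        J[] <- gr[i, j, k, , ]
        dmin <- min(dmin, det(diag(3) + J))
      }
    dmin
  })
  expect_gt(jac_min, 0.2)

  # tumor-center SI displacement is (weight at tumor) x normalized signal
  cp1 <- motion$components[[1]]
  pt <- spec$tumor$center
  w_si <- local({
    bs1 <- function(t) {
      at <- abs(t)
      ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
             ifelse(at < 2, (2 - at)^3 / 6, 0))
    }
    out <- 0
    for (a in seq_len(cp1$dims[1])) for (b in seq_len(cp1$dims[2]))
      for (cc in seq_len(cp1$dims[3])) {
        node <- cp1$origin + (c(a, b, cc) - 1) * cp1$spacing
        out <- out + prod(bs1((pt - node) / cp1$spacing)) * cp1$disp[a, b, cc, 3]
      }
    out
  })
  for (t in c(5L, 20L, 33L)) {
    d <- motion$dvf_fun(t, grid3d(1L, 1, origin = pt))
    expect_equal(d[1, 1, 1, 3], as.numeric(w_si * motion$S[t, 1]),
                 tolerance = 1e-8)
  }
})

test_that("warped tumor masks track the warped tumor intensity region", {
  # give the tumor a unique attenuation so intensity thresholding segments it
  spec <- phantom_spec(grid = grid3d(48L, 16 / 3),
                       mu = c(body = 0.02, lung = 0.005,
                              tumor = 0.045, spine = 0.035))
  ref <- make_reference_phantom(spec)
  traces <- make_breathing_traces("regular", n_t = 20L)
  motion <- make_gt_motion(traces, spec)
  t <- which.max(abs(motion$S[, 1]))
  mask_w <- gt_tumor_mask(motion, t, ref$tumor_mask)
  it <- warp_image(ref$volume, motion$dvf_fun(t, spec$grid), fill = 0)
  g <- spec$grid
  left <- array(rep(axis_coords(g, 1) < -25, prod(g$shape[2:3])), g$shape)
  # 0.025 is the lung/tumor midpoint, matching the mask's 0.5 threshold
  intens <- unclass(it) > 0.025 & left
  inter <- sum(intens & (unclass(mask_w) == 1))
  expect_gt(2 * inter / (sum(intens) + sum(mask_w)), 0.9)
})

test_that("simulated scans compose warp and projection exactly", {
  spec <- phantom_spec(grid = grid3d(32L, 8))
  geom <- cbct_geometry(n_proj = 8L, detector_px = c(48L, 48L),
                        detector_spacing = c(9.6, 9.6))
  sim <- simulate_case("regular", spec, geom, seed = 5)
  t <- 6L
  manual <- forward_project(
    warp_image(sim$phantom, sim$motion$dvf_fun(t, spec$grid), fill = 0),
    geom, t)
  expect_identical(sim$projections$data[, , t], manual)

  # zero-amplitude motion reproduces the static phantom's projections
  tr0 <- make_breathing_traces("regular", n_t = 8L,
                               diaphragm_amplitude = 1e-9,
                               chest_amplitude = 1e-9)
  m0 <- make_gt_motion(tr0, spec)
  sim0 <- simulate_scan(sim$phantom, m0, geom)
  stat <- forward_project(sim$phantom, geom, t)
  expect_equal(sim0$data[, , t], stat, tolerance = 1e-6)

  expect_equal(geom$sid, 1000)
  expect_equal(geom$sdd, 1536)
})
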