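# direct per-point tensor-product cubic B-spline evaluation: the pointwise
# oracle for the FFD
bs1 <- function(t) {
  at <- abs(t)
  ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
         ifelse(at < 2, (2 - at)^3 / 6, 0))
}

ffd_point_oracle <- function(cpg, pt) {
  out <- numeric(3)
  for (a in seq_len(cpg$dims[1])) for (b in seq_len(cpg$dims[2]))
    for (cc in seq_len(cpg$dims[3])) {
      node <- cpg$origin + (c(a, b, cc) - 1) * cpg$spacing
      w <- prod(bs1((pt - node) / cpg$spacing))
      if (w > 0) out <- out + w * cpg$disp[a, b, cc, ]
    }
  out
}

test_that("FFD evaluation: zero, partition of unity, pointwise oracle", {
  g <- grid3d(16L, 4)
  cpg <- make_control_grid(g, 32)
  expect_equal(max(abs(ffd_to_dvf(cpg, g))), 0)

  # uniform node translation -> uniform field (partition of unity)
  cpg$disp[, , , 1] <- 3.2; cpg$disp[, , , 2] <- -1.7; cpg$disp[, , , 3] <- 0.45
  d <- ffd_to_dvf(cpg, g)
  expect_lt(max(abs(d[, , , 1] - 3.2)), 1e-6)
  expect_lt(max(abs(d[, , , 2] + 1.7)), 1e-6)
  expect_lt(max(abs(d[, , , 3] - 0.45)), 1e-6)

  # single displaced node matches the tensor-product basis oracle
  cpg$disp[] <- 0
  cpg$disp[4, 5, 4, 1] <- 1
  d <- ffd_to_dvf(cpg, g)
  for (idx in list(c(3L, 7L, 5L), c(8L, 8L, 8L), c(12L, 4L, 9L))) {
    pt <- g$origin + (idx - 1) * g$spacing
    expect_equal(d[idx[1], idx[2], idx[3], ], ffd_point_oracle(cpg, pt),
                 tolerance = 1e-6)
  }
})

test_that("FFD evaluation is linear in the node displacements", {
  set.seed(2)
  g <- grid3d(12L, 4)
  cpg <- make_control_grid(g, 16)
  a <- array(rnorm(prod(cpg$dims) * 3), c(cpg$dims, 3))
  b <- array(rnorm(prod(cpg$dims) * 3), c(cpg$dims, 3))
  ca <- cpg; ca$disp <- a
  cb <- cpg; cb$disp <- b
  cab <- cpg; cab$disp <- 2 * a - 0.5 * b
  expect_equal(unclass(ffd_to_dvf(cab, g)),
               2 * unclass(ffd_to_dvf(ca, g)) - 0.5 * unclass(ffd_to_dvf(cb, g)),
               tolerance = 1e-12)
})

test_that("FFD adjoint satisfies the inner-product identity", {
  set.seed(3)
  g <- grid3d(12L, 4)
  cpg <- make_control_grid(g, 16)
  cpg$disp <- array(rnorm(prod(cpg$dims) * 3), c(cpg$dims, 3))
  field <- array(rnorm(prod(g$shape) * 3), c(g$shape, 3))
  lhs <- sum(unclass(ffd_to_dvf(cpg, g)) * field)
  adj <- dvf_adjoint_to_cpg(field, cpg, g)
  rhs <- sum(cpg$disp * adj$disp)
  expect_equal(lhs, rhs, tolerance = 1e-6 * abs(lhs))
  zero <- dvf_adjoint_to_cpg(array(0, c(g$shape, 3)), cpg, g)
  expect_equal(max(abs(zero$disp)), 0)
})

test_that("FFD adjoint of a constant field is equal on interior nodes", {
  g <- grid3d(24L, 2)
  cpg <- make_control_grid(g, 8)
  field <- array(0, c(g$shape, 3)); field[, , , 1] <- 1
  adj <- dvf_adjoint_to_cpg(field, cpg, g)
  # nodes whose 4^3 support lies fully inside the image share the same weight
  img_min <- g$origin[1]; img_max <- g$origin[1] + (g$shape[1] - 1) * g$spacing[1]
  pos <- cpg$origin[1] + (seq_len(cpg$dims[1]) - 1) * cpg$spacing[1]
  sel <- which(pos - 2 * cpg$spacing[1] >= img_min &
               pos + 2 * cpg$spacing[1] <= img_max)
  expect_gte(length(sel), 2)
  interior <- adj$disp[sel, sel, sel, 1]
  expect_lt(diff(range(interior)) / mean(interior), 1e-6)
})

test_that("warp_image: identity, integer shift, inversion round trip", {
  set.seed(4)
  vol <- blob_volume(16L, 4)
  g <- vol_grid(vol)
  expect_equal(unclass(warp_image(vol, zero_dvf(g))), unclass(vol),
               tolerance = 1e-14)

  shift <- zero_dvf(g); shift[, , , 1] <- 4
  w <- warp_image(vol, dense_dvf(unclass(shift), g$spacing, g$origin),
                  fill = 0)
  expect_equal(unclass(w)[1:15, , ], unclass(vol)[2:16, , ], tolerance = 1e-14)

  # smooth field, warp then warp by the numerical inverse; the image must be
  # smooth relative to the voxel size for the interpolation error to stay
  # within the round-trip budget
  xs <- axis_coords(g, 1)
  smooth <- volume3d(outer(outer(exp(-xs^2 / (2 * 20^2)),
                                 exp(-(xs - 6)^2 / (2 * 22^2))),
                           exp(-(xs + 4)^2 / (2 * 20^2))), g$spacing)
  cpg <- make_control_grid(g, 24)
  set.seed(40)
  cpg$disp <- array(rnorm(prod(cpg$dims) * 3, sd = 2), c(cpg$dims, 3))
  d <- ffd_to_dvf(cpg, g)
  inv <- invert_dvf(d, tol = 1e-4)
  w1 <- warp_image(smooth, d, fill = 0)
  w2 <- warp_image(w1, inv, fill = 0)
  core <- array(FALSE, g$shape); core[4:13, 4:13, 4:13] <- TRUE
  dr <- diff(range(smooth))
  expect_lt(max(abs(unclass(w2) - unclass(smooth))[core]), 0.02 * dr)
})

test_that("cubic warp agrees with linear warp on smooth images", {
  g <- grid3d(16L, 4)
  xs <- axis_coords(g, 1)
  vol <- volume3d(outer(outer(exp(-xs^2 / (2 * 20^2)),
                              exp(-(xs - 5)^2 / (2 * 20^2))),
                        exp(-xs^2 / (2 * 24^2))), g$spacing)
  cpg <- make_control_grid(g, 32)
  set.seed(41)
  cpg$disp <- array(rnorm(prod(cpg$dims) * 3, sd = 3), c(cpg$dims, 3))
  d <- ffd_to_dvf(cpg, g)
  wl <- warp_image(vol, d, interp = "linear", fill = 0)
  wc <- warp_image(vol, d, interp = "cubic", fill = 0)
  # the two modes share samples only where both stencils are in bounds
  core <- array(FALSE, g$shape); core[3:14, 3:14, 3:14] <- TRUE
  expect_lt(max(abs(unclass(wl) - unclass(wc))[core]),
            0.02 * diff(range(vol)))
})

test_that("intensity gradient term: constant, ramp, finite differences", {
  g <- grid3d(12L, 4)
  const <- volume3d(array(7, g$shape), g$spacing)
  gr <- intensity_gradient_term(const, zero_dvf(g))
  expect_equal(max(abs(gr)), 0)

  # linear ramp in world x: gradient (1, 0, 0) everywhere in the interior
  xs <- axis_coords(g, 1)
  ramp <- volume3d(array(rep(xs, times = 12 * 12), g$shape), g$spacing)
  cpg <- make_control_grid(g, 16)
  cpg$disp <- array(rnorm(prod(cpg$dims) * 3, sd = 1.5), c(cpg$dims, 3))
  d <- ffd_to_dvf(cpg, g)
  gr <- intensity_gradient_term(ramp, d)
  core <- 3:10
  expect_equal(max(abs(gr[core, core, core, 1] - 1)), 0, tolerance = 1e-6)
  expect_equal(max(abs(gr[core, core, core, 2:3])), 0, tolerance = 1e-6)

  # zero displacement: linear mode reduces to central differences exactly
  vol <- blob_volume(12L, 4)
  gr <- intensity_gradient_term(vol, zero_dvf(g), interp = "linear")
  v <- unclass(vol)
  cd <- (v[3:12, , ] - v[1:10, , ]) / (2 * 4)
  expect_equal(gr[2:11, , , 1], cd, tolerance = 1e-3 * max(abs(cd)))
})

test_that("control grid refinement reproduces the same deformation", {
  set.seed(6)
  g <- grid3d(16L, 4)
  cpg <- make_control_grid(g, 32)
  cpg$disp <- array(rnorm(prod(cpg$dims) * 3, sd = 2), c(cpg$dims, 3))
  fine <- refine_control_grid(cpg)
  expect_equal(fine$spacing, cpg$spacing / 2)
  d0 <- ffd_to_dvf(cpg, g)
  d1 <- ffd_to_dvf(fine, g)
  expect_lt(max(abs(unclass(d0) - unclass(d1))), 1e-10)
})

test_that("insufficient control-grid coverage is an error", {
  g <- grid3d(16L, 4)
  cpg <- make_control_grid(g, 32)
  big <- grid3d(64L, 4)
  expect_error(ffd_to_dvf(cpg, big), "cover")
})
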