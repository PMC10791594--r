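# exact ray/axis-aligned-box intersection length (slab method): the
# Siddon-style oracle used to validate line integrals
ray_box_length <- function(src, dir, lo, hi) {
  t0 <- -Inf; t1 <- Inf
  for (a in 1:3) {
    if (abs(dir[a]) < 1e-12) {
      if (src[a] < lo[a] || src[a] > hi[a]) return(0)
    } else {
      tt <- sort(c((lo[a] - src[a]) / dir[a], (hi[a] - src[a]) / dir[a]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
  }
  max(0, t1 - t0)
}

pixel_ray <- function(geom, frame, iu, iv) {
  th <- geom$angles[frame] * pi / 180
  src <- c(cos(th), sin(th), 0) * geom$sid
  u <- (iu - (geom$nu + 1) / 2) * geom$du
  v <- (iv - (geom$nv + 1) / 2) * geom$dv
  pix <- c((geom$sid - geom$sdd) * cos(th) - u * sin(th),
           (geom$sid - geom$sdd) * sin(th) + u * cos(th), v)
  d <- pix - src
  list(src = src, dir = d / sqrt(sum(d^2)))
}

test_that("forward projection: zero input, unit-voxel impulse, analytic cube", {
  g <- grid3d(32L, 2)
  geom <- cbct_geometry(n_proj = 6L, detector_px = c(33L, 33L),
                        detector_spacing = c(2, 2))
  zero <- volume3d(array(0, g$shape), g$spacing)
  expect_equal(max(abs(forward_project(zero, geom, 1))), 0)

  # single voxel at the isocenter: the central-pixel ray passes through the
  # voxel center at every gantry angle; for the axis-aligned view the line
  # integral of the trilinear impulse equals the exact voxel chord (= spacing)
  gg <- grid3d(31L, 2)
  imp <- array(0, gg$shape); imp[16, 16, 16] <- 1
  vol <- volume3d(imp, gg$spacing)
  p <- forward_project(vol, geom, 1)  # angle 0: ray along -x
  r <- pixel_ray(geom, 1, 17, 17)
  sidd <- ray_box_length(r$src, r$dir, rep(-1, 3), rep(1, 3))
  expect_equal(sidd, 2)
  expect_equal(p[17, 17], sidd, tolerance = 1e-3)

  # homogeneous 40 mm cube, attenuation 1/mm: oblique central rays match the
  # exact chord (Siddon oracle over the cube) to interpolation tolerance
  cube <- array(0, g$shape)
  cc <- axis_coords(g, 1)
  inside <- abs(cc) <= 20
  cube[inside, inside, inside] <- 1
  vol <- volume3d(cube, g$spacing)
  for (frame in c(1L, 2L, 4L)) {
    p <- forward_project(vol, geom, frame)
    for (iu in c(15L, 17L, 19L)) {
      r <- pixel_ray(geom, frame, iu, 17)
      chord <- ray_box_length(r$src, r$dir, rep(-20, 3), rep(20, 3))
      if (chord > 30)
        expect_equal(p[iu, 17], chord, tolerance = 0.02)
    }
  }
})

test_that("forward projection is linear in the volume", {
  set.seed(5)
  g <- grid3d(12L, 4)
  geom <- cbct_geometry(n_proj = 3L, detector_px = c(16L, 16L),
                        detector_spacing = c(6, 6))
  u <- volume3d(array(rnorm(prod(g$shape)), g$shape), g$spacing)
  v <- volume3d(array(rnorm(prod(g$shape)), g$shape), g$spacing)
  comb <- volume3d(2.5 * unclass(u) - 1.25 * unclass(v), g$spacing)
  p <- forward_project(comb, geom, 2)
  expect_equal(p, 2.5 * forward_project(u, geom, 2) -
                  1.25 * forward_project(v, geom, 2), tolerance = 1e-12)
})

test_that("back projection is the exact adjoint at random angles", {
  set.seed(11)
  g <- grid3d(16L, 4)
  geom <- cbct_geometry(n_proj = 8L, detector_px = c(24L, 24L),
                        detector_spacing = c(6, 6),
                        angles = runif(8, 0, 360), times = 0:7)
  for (f in 1:8) {
    x <- volume3d(array(rnorm(prod(g$shape)), g$shape), g$spacing)
    y <- matrix(rnorm(24 * 24), 24, 24)
    Ax <- forward_project(x, geom, f)
    Aty <- back_project(y, geom, f, g)
    err <- abs(sum(Ax * y) - sum(unclass(x) * unclass(Aty))) /
      (sqrt(sum(Ax^2)) * sqrt(sum(y^2)))
    expect_lt(err, 1e-5)
  }
})

test_that("adjoint of a positive projection is positive on traversed voxels", {
  g <- grid3d(16L, 4)
  geom <- cbct_geometry(n_proj = 2L, detector_px = c(24L, 24L),
                        detector_spacing = c(6, 6))
  b <- back_project(matrix(1, 24, 24), geom, 1, g)
  expect_true(all(unclass(b) >= 0))
  # central region is traversed by many rays
  expect_true(all(unclass(b)[6:11, 6:11, 6:11] > 0))
  expect_equal(max(abs(back_project(matrix(0, 24, 24), geom, 1, g))), 0)
})

test_that("projections of a centered sphere are rotation invariant", {
  g <- grid3d(32L, 2)
  geom <- cbct_geometry(n_proj = 5L, detector_px = c(33L, 33L),
                        detector_spacing = c(2.4, 2.4))
  cc <- axis_coords(g, 1)
  r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  vol <- volume3d(array(0.02 * (r2 <= 20^2), g$shape), g$spacing)
  p1 <- forward_project(vol, geom, 1)
  for (f in 2:5) {
    pf <- forward_project(vol, geom, f)
    # voxelization staircase perturbs rim pixels; the bulk must agree closely
    expect_lt(mean(abs(pf - p1)) / max(p1), 0.015)
    expect_lt(max(abs(pf - p1)) / max(p1), 0.12)
  }
})

test_that("frame index and geometry mismatches are rejected", {
  g <- grid3d(8L, 4)
  geom <- cbct_geometry(n_proj = 3L, detector_px = c(8L, 8L),
                        detector_spacing = c(4, 4))
  vol <- volume3d(array(0, g$shape), g$spacing)
  expect_error(forward_project(vol, geom, 0), "out of range")
  expect_error(forward_project(vol, geom, 4), "out of range")
  expect_error(back_project(matrix(0, 4, 4), geom, 1, g), "do not match")
})
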