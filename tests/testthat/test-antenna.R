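mk_rec <- function(name, centroid, axis, length = 30) {
  data.frame(name = name, length = length,
             centroid_x = centroid[1], centroid_y = centroid[2],
             centroid_z = centroid[3],
             axis_x = axis[1], axis_y = axis[2], axis_z = axis[3])
}

test_that("pair_dipole bisector and baseline behave on constructed pairs", {
  # mirror-symmetric arms tilted +/-30 degrees about the x-z midline
  aL <- c(cos(pi / 6), sin(pi / 6), 0)
  aR <- c(cos(pi / 6), -sin(pi / 6), 0)
  L <- mk_rec("t_L", c(0, 10, 0), aL)
  R <- mk_rec("t_R", c(0, -10, 0), aR)
  ant <- pair_dipole(L, R, "bisector")
  expect_equal(ant$center, c(0, 0, 0))
  expect_equal(ant$axis, c(1, 0, 0), tolerance = 1e-12)
  # identical parallel arms keep their common axis
  P <- mk_rec("t_R", c(0, -10, 0), aL)
  expect_equal(pair_dipole(L, P, "bisector")$axis, aL, tolerance = 1e-12)
  # anti-parallel arms have no bisector
  Q <- mk_rec("t_R", c(0, -10, 0), -aL)
  expect_error(pair_dipole(L, Q, "bisector"), "baseline")
  expect_silent(pair_dipole(L, Q, "baseline"))
})

test_that("the two axis strategies are distinct for near-parallel arms", {
  # near-parallel arms: the tip-to-tip baseline is dominated by the
  # lateral centroid offset, so it is far from the arm direction
  rec <- default_records()
  L <- rec[rec$name == "anterior_L", ]
  R <- rec[rec$name == "anterior_R", ]
  b1 <- pair_dipole(L, R, "bisector")$axis
  b2 <- pair_dipole(L, R, "baseline")$axis
  ang <- acos(min(1, abs(sum(b1 * b2)))) * 180 / pi
  expect_equal(ang, 73.3, tolerance = 0.05)
  # both anchor the same centre
  expect_equal(pair_dipole(L, R, "baseline")$center,
               pair_dipole(L, R, "bisector")$center)
})

test_that("dipole gain follows the short-dipole sin^2/r^2 pattern", {
  ant <- antenna_pair("t", c(0, 0, 0), c(0, 0, 1))
  expect_equal(dipole_gain(c(0, 0, 5), ant), 0)
  expect_equal(dipole_gain(c(0, 0, -2), ant), 0)
  expect_equal(dipole_gain(c(1, 0, 0), ant), 1)
  expect_equal(dipole_gain(c(0, 2, 0), ant), 0.25)
  th <- pi / 5
  expect_equal(dipole_gain(3 * c(sin(th), 0, cos(th)), ant),
               sin(th)^2 / 9, tolerance = 1e-12)
  expect_error(dipole_gain(c(0, 0, 0), ant), "centre")
})

test_that("iso-gain surface points satisfy the level-set equation", {
  ant <- antenna_pair("t", c(3, -2, 1), c(0.3, -0.5, sqrt(1 - 0.34)))
  level <- 0.004
  pts <- gain_isosurface_points(ant, level, n = 48)
  g <- dipole_gain(pts, ant)
  expect_lt(max(abs(g - level)) / level, 0.02)
  expect_gt(nrow(pts), 500)
})

test_that("the iso-gain surface is the predicted horn torus", {
  ant <- antenna_pair("t", c(0, 0, 0), c(0, 0, 1))
  level <- 0.0025   # b = 1 / (2 sqrt(level)) = 10
  fit <- gain_to_torus(ant, level, n = 56)
  expect_equal(fit$b, 10, tolerance = 0.01)
  expect_lt(abs(attr(fit, "raw_a")), 0.1)
  expect_lt(attr(fit, "fit_rms"), 0.05)
  # fitted torus centre stays on the antenna axis
  expect_lt(sqrt(sum((fit$center - ant$center)[1:2]^2)), 0.5)
  # lower gain level, larger doughnut
  Rs <- sapply(c(0.01, 0.0025, 0.001), function(lv)
    gain_to_torus(ant, lv, n = 48)$R)
  expect_true(all(diff(Rs) > 0))
})

test_that("torus refit recovers an exactly-constructed point cloud", {
  t0 <- torus(c(5, 6, 7), c(0, 1, 0), a = 40, b = 12)
  set.seed(2)
  u <- runif(4000, 0, 2 * pi); v <- runif(4000, 0, 2 * pi)
  # surface of revolution in the torus frame (axis = y)
  rho <- t0$R + t0$b * cos(v)
  pts <- cbind(t0$center[1] + rho * cos(u),
               t0$center[2] + t0$b * sin(v),
               t0$center[3] + rho * sin(u))
  fit <- fit_torus_to_points(pts, t0$center, t0$axis)
  expect_equal(fit$a, 40, tolerance = 0.4)
  expect_equal(fit$b, 12, tolerance = 0.12)
  expect_lt(attr(fit, "fit_rms"), 1e-6)
})

test_that("torus membership agrees with the implicit inequality", {
  t0 <- torus(c(1, 2, 3), c(0.48, -0.6, 0.64), a = 18, b = 7)
  expect_false(torus_contains(t0$center, t0))
  # a point on the tube's core circle
  perp <- c(0.6, 0.8, 0) - sum(c(0.6, 0.8, 0) * t0$axis) * t0$axis
  perp <- perp / sqrt(sum(perp^2))
  expect_true(torus_contains(t0$center + t0$R * perp, t0))
  # independent brute-force oracle: rotate into the torus frame with an
  # explicitly constructed orthonormal basis and apply the inequality
  set.seed(9)
  n <- 1e6
  pts <- cbind(runif(n, -30, 32), runif(n, -28, 34), runif(n, -26, 36))
  e3 <- t0$axis
  e1 <- c(1, 0, 0) - e3[1] * e3; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  rel <- sweep(pts, 2L, t0$center)
  x <- rel %*% e1; y <- rel %*% e2; z <- rel %*% e3
  oracle <- (sqrt(x^2 + y^2) - t0$R)^2 + z^2 <= t0$b^2
  expect_identical(unname(torus_contains(pts, t0)), as.vector(oracle))
})

test_that("voxelised torus volume approaches 2 pi^2 R b^2", {
  t0 <- torus(c(0, 0, 0), c(0, 0.6, 0.8), a = 14, b = 6)
  v_true <- torus_volume(t0)
  err <- sapply(c(2, 1), function(h) {
    m <- voxelize_torus(t0, h)
    abs(sum(m$mask) * h^3 - v_true) / v_true
  })
  expect_lt(err[2], 0.03)
  expect_lt(err[2], err[1])
})

test_that("Euler characteristics distinguish balls from tori", {
  n <- 19L
  idx <- as.matrix(expand.grid(i = 1:n, j = 1:n, k = 1:n))
  r <- sqrt(rowSums(sweep(idx - 0.5, 2L, rep(n / 2, 3))^2))
  ball <- array(r <= 7, dim = rep(n, 3))
  expect_equal(euler_characteristic(ball), 1L)
  mesh <- boundary_quad_mesh(ball, 1)
  expect_equal(mesh_euler_characteristic(mesh), 2L)

  t0 <- torus(c(0, 0, 0), c(0, 0, 1), a = 8, b = 5)
  vox <- voxelize_torus(t0, 1)
  expect_equal(euler_characteristic(vox$mask), 0L)
  tmesh <- boundary_quad_mesh(vox$mask, 1, vox$origin)
  expect_equal(mesh_euler_characteristic(tmesh), 0L)
})

test_that("dipole iso-gain regions have toroidal topology", {
  ant <- antenna_pair("t", c(0, 0, 0), c(0.2, 0.4, sqrt(0.8)))
  for (level in c(0.01, 0.0025)) {
    gr <- gain_region_mask(ant, level, voxel_size = 1 / (2 * sqrt(level)) / 10)
    expect_equal(euler_characteristic(gr$mask), 0L)
  }
})

test_that("PLY export writes a well-formed mesh file", {
  t0 <- torus(c(0, 0, 0), c(0, 0, 1), a = 5, b = 3)
  mesh <- torus_mesh(t0, 1)
  f <- tempfile(fileext = ".ply")
  on.exit(unlink(f))
  write_ply(mesh, f)
  lines <- readLines(f)
  expect_equal(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "",
                       grep("element vertex", lines, value = TRUE)))
  expect_equal(nv, nrow(mesh$vertices))
  expect_equal(length(lines), 9 + nrow(mesh$vertices) + nrow(mesh$quads))
})

test_that("overlap of identical tori equals the single torus", {
  t0 <- torus(c(0, 0, 0), c(0, 0, 1), a = 12, b = 6)
  ov <- overlap_region(list(t0, t0, t0), voxel_size = 0.75)
  expect_equal(ov$volume, torus_volume(t0), tolerance = 0.03)
  expect_equal(ov$equivalent_sphere_radius,
               (3 * ov$volume / (4 * pi))^(1 / 3))
})

test_that("far-separated tori have empty overlap, reported as volume 0", {
  ts <- lapply(c(0, 100, 200), function(d)
    torus(c(d, 0, 0), c(0, 0, 1), a = 5, b = 3))
  ov <- overlap_region(ts, voxel_size = 1)
  expect_true(ov$empty)
  expect_equal(ov$volume, 0)
  expect_true(all(is.na(ov$centroid)))
})

test_that("overlap is order-invariant and monotone under dilation", {
  ts <- list(torus(c(0, 0, 0), c(0, 0, 1), 10, 6),
             torus(c(4, 1, 0), c(0, 1, 0), 9, 7),
             torus(c(-2, 3, 1), c(1, 0, 0), 11, 6))
  bb <- rbind(rep(-32, 3), rep(32, 3))
  ov1 <- overlap_region(ts, voxel_size = 1, bbox = bb)
  ov2 <- overlap_region(rev(ts), voxel_size = 1, bbox = bb)
  expect_identical(ov1$mask, ov2$mask)
  # nested tori (same core ring, fatter tube) give a superset overlap
  fat <- lapply(ts, function(t) torus(t$center, t$axis,
                                      max(0, t$R - 1.5 * t$b), 1.5 * t$b))
  ov3 <- overlap_region(fat, voxel_size = 1, bbox = bb)
  expect_true(all(ov3$mask[ov1$mask]))
  expect_gte(ov3$volume, ov1$volume)
  # a bbox that misses the tori is an error
  expect_error(overlap_region(ts, bbox = rbind(rep(0, 3), rep(5, 3))),
               "bbox")
})

test_that("the exterior clip plane restricts the overlap half-space", {
  t0 <- torus(c(0, 0, 0), c(0, 0, 1), a = 8, b = 5)
  ov <- overlap_region(list(t0), voxel_size = 1,
                       clip_plane = list(point = c(0, 0, 0),
                                         normal = c(1, 0, 0)))
  idx <- which(ov$mask, arr.ind = TRUE)
  xs <- ov$origin[1] + (idx[, 1] - 0.5) * 1
  expect_true(all(xs >= 0))
  expect_equal(ov$volume, torus_volume(t0) / 2, tolerance = 0.05)
})

test_that("strike-range calibration uses a closed interval", {
  t0 <- torus(c(150, 0, 0), c(0, 1, 0), a = 2, b = 4)
  ov <- overlap_region(list(t0), voxel_size = 0.5)
  ctr <- ov$centroid
  d <- sqrt(sum(ctr^2))
  res <- calibrate_strike_range(ov, c(0, 0, 0))
  expect_true(res$in_range)
  expect_equal(res$distance, d, tolerance = 1e-6)
  expect_false(calibrate_strike_range(ov, c(-300, 0, 0))$in_range)
  # boundary at exactly 200 mm is inside the closed interval
  res2 <- calibrate_strike_range(ov, ctr + c(200, 0, 0))
  expect_true(res2$in_range)
  empty <- overlap_region(lapply(c(0, 100, 200), function(d)
    torus(c(d, 0, 0), c(0, 0, 1), 5, 3)), voxel_size = 1)
  expect_error(calibrate_strike_range(empty, c(0, 0, 0)), "empty")
})
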