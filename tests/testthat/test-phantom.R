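test_that("capsule rasterisation matches the analytic volume and converges", {
  # 2 mm radius, 30 mm cylinder: pi r^2 L + 4/3 pi r^3 = 410.5 mm^3
  v_true <- capsule_volume(30, 2)
  expect_equal(v_true, pi * 4 * 30 + 4 / 3 * pi * 8)
  rel_err <- sapply(c(1, 0.5, 0.25), function(h) {
    shape <- rep(as.integer(ceiling(40 / h)), 3L)
    grid <- capsule_grid(h, shape)
    ctr <- shape * h / 2
    spec <- tubule_spec(1L, "t", 55, 30, length = 30, radius = 2,
                        origin = ctr - 15 * angles_to_unit_vector(55, 30))
    m <- rasterize_capsule(spec, grid)
    abs(sum(m) * h^3 - v_true) / v_true
  })
  expect_lt(rel_err[2], 0.05)  # within 5% at 0.5 mm voxels
  expect_true(all(diff(rel_err) < 0))  # strictly decreasing with h
})

test_that("invalid capsules are rejected", {
  grid <- capsule_grid(1, c(40L, 40L, 40L))
  expect_error(tubule_spec(1L, "t", 10, 0, length = 0, radius = 2,
                           origin = c(20, 20, 20)), "length")
  expect_error(tubule_spec(1L, "t", 10, 0, length = 5, radius = -1,
                           origin = c(20, 20, 20)), "radius")
  big <- tubule_spec(1L, "runaway", 0, 0, length = 100, radius = 2,
                     origin = c(20, 20, 20))
  expect_error(rasterize_capsule(big, grid), "runaway")
})

test_that("overlapping structures abort phantom generation", {
  grid_shape <- c(50L, 50L, 50L)
  t1 <- tubule_spec(1L, "a", 90, 0, length = 20, radius = 3,
                    origin = c(25, 25, 12))
  t2 <- tubule_spec(2L, "b", 90, 90, length = 20, radius = 3,
                    origin = c(25, 12, 25))  # crosses t1
  spec <- phantom_spec(list(t1, t2), sac_center = c(8, 8, 8),
                       sac_radii = c(3, 3, 3),
                       mouth_landmark = c(0, 0, 0),
                       snout_landmark = c(0, 0, 0),
                       voxel_size = 1, grid_shape = grid_shape)
  expect_error(make_head_phantom(spec), "overlaps")
})

test_that("default phantom carries all seven labels and exact ground truth", {
  ph <- default_phantom()
  labs <- sort(unique(as.integer(ph$volume$labels)))
  expect_equal(labs, 0:7)
  expect_equal(nrow(ph$truth), 6L)
  # the generator's ground truth is the published specimen table
  expect_equal(ph$truth$alpha_v, reference_orientations()$alpha_v)
  expect_equal(ph$truth$alpha_h, reference_orientations()$alpha_h)
  expect_equal(ph$truth$total_length, reference_dimensions()$length)
  expect_equal(ph$truth$volume, reference_dimensions()$volume,
               tolerance = 1e-8)
})

test_that("a one-tubule phantom yields two nonzero labels", {
  t1 <- tubule_spec(1L, "solo", 90, 0, length = 15, radius = 2,
                    origin = c(20, 20, 10))
  spec <- phantom_spec(list(t1), sac_center = c(10, 10, 10),
                       sac_radii = c(4, 3, 3),
                       mouth_landmark = c(0, 0, 0),
                       snout_landmark = c(0, 0, 0),
                       voxel_size = 1, grid_shape = c(40L, 40L, 40L),
                       sac_label_id = 2L)
  ph <- make_head_phantom(spec)
  expect_equal(sort(unique(as.integer(ph$volume$labels))), 0:2)
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  t1 <- tubule_spec(1L, "solo", 70, 40, length = 15, radius = 2,
                    origin = c(10, 10, 10))
  spec <- phantom_spec(list(t1), sac_center = c(30, 30, 30),
                       sac_radii = c(4, 3, 3),
                       mouth_landmark = c(0, 0, 0),
                       snout_landmark = c(0, 0, 0),
                       voxel_size = 1, grid_shape = c(40L, 40L, 40L))
  a <- make_head_phantom(spec, seed = 7L, jitter = TRUE)
  b <- make_head_phantom(spec, seed = 7L, jitter = TRUE)
  expect_identical(a$volume$labels, b$volume$labels)
  c_ <- make_head_phantom(spec, seed = 8L, jitter = TRUE)
  expect_false(identical(a$volume$labels, c_$volume$labels))
  # jitter moves boundaries by at most one voxel
  raw <- make_head_phantom(spec)$volume$labels
  changed <- which((a$volume$labels == 1L) != (raw == 1L), arr.ind = TRUE)
  if (nrow(changed)) {
    core <- which(raw == 1L, arr.ind = TRUE)
    dmin <- apply(changed, 1L, function(p)
      min(sqrt(colSums((t(core) - p)^2))))
    expect_lte(max(dmin), sqrt(3))
  }
})

test_that("NIfTI round trip preserves labels and voxel size", {
  t1 <- tubule_spec(1L, "solo", 90, 0, length = 10, radius = 2,
                    origin = c(15, 15, 8))
  spec <- phantom_spec(list(t1), sac_center = c(8, 8, 8),
                       sac_radii = c(3, 3, 3),
                       mouth_landmark = c(0, 0, 0),
                       snout_landmark = c(0, 0, 0),
                       voxel_size = 0.5, grid_shape = c(60L, 60L, 40L))
  ph <- make_head_phantom(spec)
  f <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(f))
  write_labeled_volume(ph$volume, f)
  back <- read_labeled_volume(f)
  expect_identical(back$labels, ph$volume$labels)
  expect_equal(back$voxel_size, 0.5)
})

test_that("float-valued NIfTI input is rejected, anisotropic accepted", {
  f <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(f))
  img <- RNifti::asNifti(array(runif(8 * 8 * 8), dim = c(8, 8, 8)))
  RNifti::writeNifti(img, f)
  expect_error(read_labeled_volume(f), "integer")

  img2 <- RNifti::asNifti(array(1L, dim = c(6, 6, 6)))
  RNifti::pixdim(img2) <- c(0.5, 1, 2)
  RNifti::writeNifti(img2, f, datatype = "int32")
  aniso <- read_labeled_volume(f)
  expect_equal(aniso$voxel_size, c(0.5, 1, 2))
  # volumes must use the per-axis sizes
  expect_equal(label_volume(aniso, 1L), 6 * 6 * 6 * 0.5 * 1 * 2)
})
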