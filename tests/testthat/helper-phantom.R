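# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(value)
  .fixtures[[key]]
}

default_phantom <- function() {
  memo("phantom", make_head_phantom(latimeria_phantom_spec()))
}

# raw-mask morphometry of the default phantom (no smoothing: fast)
default_records <- function() {
  memo("records",
       tubule_morphometry(default_phantom()$volume, sac_label = 7L))
}

# one full default pipeline run (SWD smoothing, overlap, sweep)
default_pipeline <- function() {
  memo("pipeline", run_pipeline(pipeline_config()))
}

# a single-capsule grid: a phantom_spec shell whose only role is to carry
# voxel size and grid shape for rasterize_capsule()
capsule_grid <- function(voxel_size = 1, shape = c(60L, 60L, 60L)) {
  phantom_spec(tubules = list(),
               sac_center = shape * voxel_size / 2,
               sac_radii = c(1, 1, 1) * voxel_size,
               mouth_landmark = c(0, 0, 0), snout_landmark = c(0, 0, 0),
               voxel_size = voxel_size, grid_shape = shape)
}

# rasterise one capsule with given orientation in its own grid; returns
# the mask plus the ground truth needed for recovery checks
make_capsule <- function(alpha_v, alpha_h, total_length = 30, radius = 3,
                         voxel_size = 1) {
  ext <- total_length
  shape <- rep(as.integer(ceiling((ext + 2 * radius + 8) / voxel_size)), 3L)
  grid <- capsule_grid(voxel_size, shape)
  v <- angles_to_unit_vector(alpha_v, alpha_h)
  center <- shape * voxel_size / 2
  origin <- center - (ext / 2) * v + radius * v
  spec <- tubule_spec(1L, "capsule", alpha_v, alpha_h,
                      length = ext - 2 * radius, radius = radius,
                      origin = origin)
  list(mask = rasterize_capsule(spec, grid), spec = spec,
       voxel_size = voxel_size, origin = origin,
       axis = v, total_length = ext)
}

# recover the oriented principal axis of a capsule mask, using the
# proximal (origin) end as the anatomical anchor
recover_axis <- function(mask, voxel_size, origin) {
  ax <- principal_axis(inertia_tensor(mask, voxel_size))
  orient_axis(ax, mask, voxel_size, origin)
}

angdiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
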