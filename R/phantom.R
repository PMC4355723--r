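#' Tubule specification for the head phantom
#'
#' Describes one tubule as a capsule: a cylinder of the given `length`
#' capped by hemispheres of the given `radius`, starting at `origin` (the
#' rostral-sac end) and running along the axis given by the orientation
#' angles. The full rostral-caudal extent of the capsule is therefore
#' `length + 2 * radius`.
#'
#' @param label_id Positive integer, unique within a phantom.
#' @param name Structure name (e.g. `"anterior_L"`).
#' @param alpha_v,alpha_h Orientation angles in degrees (see
#'   [axis_convention()]).
#' @param length Cylinder extent in mm, `> 0`.
#' @param radius Capsule radius in mm, `> 0`.
#' @param origin 3-vector, mm: proximal (sac-end) tip of the capsule.
#' @return Object of class `tubule_spec`.
#' @export
tubule_spec <- function(label_id, name, alpha_v, alpha_h, length, radius,
                        origin) {
  stopifnot(length(label_id) == 1L, label_id > 0,
            label_id == round(label_id))
  if (alpha_v < 0 || alpha_v > 180)
    stop("alpha_v must lie in [0, 180] degrees")
  if (alpha_h <= -180 || alpha_h > 180)
    stop("alpha_h must lie in (-180, 180] degrees")
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  origin <- as.numeric(origin)
  stopifnot(base::length(origin) == 3L, all(is.finite(origin)))
  structure(
    list(label_id = as.integer(label_id), name = as.character(name),
         alpha_v = alpha_v, alpha_h = alpha_h,
         length = length, radius = radius, origin = origin),
    class = "tubule_spec")
}

#' Analytic capsule volume
#'
#' Volume of a cylinder of length `length` and radius `radius` capped by
#' two hemispheres: `pi r^2 L + 4/3 pi r^3`.
#'
#' @param length Cylinder extent, mm.
#' @param radius Capsule radius, mm.
#' @return Volume in mm^3.
#' @export
capsule_volume <- function(length, radius) {
  pi * radius^2 * length + 4 / 3 * pi * radius^3
}

#' Solve the capsule radius matching a target volume and overall extent
#'
#' Given a tubule's measured volume and end-to-end length (caps included),
#' finds the radius `r` such that a capsule with cylinder extent
#' `total_length - 2 r` has the target volume. Used to build phantoms whose
#' tubules match published volume/length pairs simultaneously.
#'
#' @param volume Target capsule volume, mm^3.
#' @param total_length End-to-end capsule extent (`length + 2 r`), mm.
#' @return Radius in mm.
#' @export
capsule_radius_for <- function(volume, total_length) {
  stopifnot(volume > 0, total_length > 0)
  f <- function(r) capsule_volume(total_length - 2 * r, r) - volume
  upper <- total_length / 2 * (1 - 1e-9)
  if (f(upper) < 0)
    stop("volume too large for the given total length (exceeds a sphere)")
  stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
}

#' Phantom specification
#'
#' Geometry of a synthetic labelled head volume: a list of tubule capsules,
#' an ellipsoidal rostral sac (the medial cavity holding the sensory
#' epithelia), and mouth/snout landmarks, on an isotropic voxel grid whose
#' corner sits at the coordinate origin.
#'
#' @param tubules List of [tubule_spec()] objects (typically 6).
#' @param sac_center,sac_radii Ellipsoid centre and semi-axes, mm.
#' @param mouth_landmark 3-vector, mm: centre of the mouth opening.
#' @param snout_landmark 3-vector, mm: anterior-most point of the snout
#'   (reference for strike-range distances).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param grid_shape Integer 3-vector of grid dimensions.
#' @param sac_label_id Label for the sac (default: max tubule label + 1).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(tubules, sac_center, sac_radii, mouth_landmark,
                         snout_landmark, voxel_size = 1,
                         grid_shape = c(120L, 100L, 90L),
                         sac_label_id = NULL) {
  stopifnot(is.list(tubules),
            all(vapply(tubules, inherits, logical(1), "tubule_spec")))
  ids <- vapply(tubules, `[[`, integer(1), "label_id")
  if (anyDuplicated(ids))
    stop("tubule label_ids must be unique")
  if (is.null(sac_label_id))
    sac_label_id <- if (length(ids)) max(ids) + 1L else 1L
  if (sac_label_id %in% ids)
    stop("sac_label_id collides with a tubule label")
  stopifnot(length(voxel_size) == 1L, voxel_size > 0,
            length(grid_shape) == 3L, all(grid_shape >= 1))
  structure(
    list(tubules = tubules,
         sac_center = as.numeric(sac_center),
         sac_radii = as.numeric(sac_radii),
         mouth_landmark = as.numeric(mouth_landmark),
         snout_landmark = as.numeric(snout_landmark),
         voxel_size = as.numeric(voxel_size),
         grid_shape = as.integer(grid_shape),
         sac_label_id = as.integer(sac_label_id)),
    class = "phantom_spec")
}

tubule_axis <- function(spec) angles_to_unit_vector(spec$alpha_v, spec$alpha_h)

#' Rasterise a capsule tubule onto a phantom grid
#'
#' Marks every voxel whose centre lies within distance `radius` of the
#' capsule's core segment. Deterministic for a fixed spec.
#'
#' @param spec A [tubule_spec()].
#' @param grid A [phantom_spec()] (only voxel size / grid shape are used).
#' @return Logical 3D array of the grid shape.
#' @export
rasterize_capsule <- function(spec, grid) {
  stopifnot(inherits(spec, "tubule_spec"), inherits(grid, "phantom_spec"))
  h <- grid$voxel_size
  dims <- grid$grid_shape
  v <- tubule_axis(spec)
  p0 <- spec$origin
  p1 <- spec$origin + spec$length * v
  lo <- pmin(p0, p1) - spec$radius
  hi <- pmax(p0, p1) + spec$radius
  if (any(lo < 0) || any(hi > dims * h))
    stop("tubule '", spec$name, "' (label ", spec$label_id,
         ") does not fit inside the grid")
  ilo <- pmax(1L, floor(lo / h - 0.5) + 1L)
  ihi <- pmin(dims, ceiling(hi / h + 0.5))
  mask <- array(FALSE, dim = dims)
  idx <- as.matrix(expand.grid(i = ilo[1]:ihi[1], j = ilo[2]:ihi[2],
                               k = ilo[3]:ihi[3]))
  pts <- voxel_centers(idx, h)
  d <- point_segment_distance(pts, p0, p1)
  inside <- d <= spec$radius
  mask[idx[inside, , drop = FALSE]] <- TRUE
  mask
}

#' Distance from points to a segment
#' @param pts n x 3 matrix; `p0`, `p1` segment endpoints.
#' @keywords internal
point_segment_distance <- function(pts, p0, p1) {
  u <- p1 - p0
  len2 <- sum(u^2)
  rel <- sweep(pts, 2L, p0)
  t <- if (len2 > 0) pmin(1, pmax(0, (rel %*% u) / len2)) else
    matrix(0, nrow(pts), 1L)
  proj <- rel - t %*% t(u)
  sqrt(rowSums(proj^2))
}

rasterize_ellipsoid <- function(center, radii, grid) {
  h <- grid$voxel_size
  dims <- grid$grid_shape
  lo <- center - radii
  hi <- center + radii
  if (any(lo < 0) || any(hi > dims * h))
    stop("sac ellipsoid does not fit inside the grid")
  ilo <- pmax(1L, floor(lo / h - 0.5) + 1L)
  ihi <- pmin(dims, ceiling(hi / h + 0.5))
  mask <- array(FALSE, dim = dims)
  idx <- as.matrix(expand.grid(i = ilo[1]:ihi[1], j = ilo[2]:ihi[2],
                               k = ilo[3]:ihi[3]))
  pts <- voxel_centers(idx, h)
  q <- sweep(sweep(pts, 2L, center), 2L, radii, "/")
  inside <- rowSums(q^2) <= 1
  mask[idx[inside, , drop = FALSE]] <- TRUE
  mask
}

#' Generate a labelled head phantom
#'
#' Rasterises every tubule capsule and the sac ellipsoid of a
#' [phantom_spec()] into a [labeled_volume()], together with a ground-truth
#' table carrying every spec field. Overlapping structures are an error:
#' labels must be pairwise disjoint.
#'
#' Optional segmentation noise perturbs each label boundary by at most one
#' voxel: boundary voxels are eroded and background voxels adjacent to the
#' label are dilated, each independently with probability `jitter_prob`,
#' under the given seed. Dilation never claims voxels of another label.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed controlling the jitter (ignored when
#'   `jitter = FALSE`); the noiseless phantom is fully deterministic.
#' @param jitter Apply boundary jitter?
#' @param jitter_prob Per-voxel flip probability on the boundary.
#' @return List with elements `volume` (a [labeled_volume()]) and `truth`
#'   (a `data.frame` of per-structure ground truth).
#' @export
make_head_phantom <- function(spec, seed = 1L, jitter = FALSE,
                              jitter_prob = 0.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  labels <- array(0L, dim = dims)
  for (tb in spec$tubules) {
    m <- rasterize_capsule(tb, spec)
    clash <- labels[m]
    if (any(clash != 0L))
      stop("tubule '", tb$name, "' overlaps label(s) ",
           paste(unique(clash[clash != 0L]), collapse = ", "),
           " after rasterization")
    labels[m] <- tb$label_id
  }
  sac <- rasterize_ellipsoid(spec$sac_center, spec$sac_radii, spec)
  clash <- labels[sac]
  if (any(clash != 0L))
    stop("sac overlaps label(s) ",
         paste(unique(clash[clash != 0L]), collapse = ", "))
  labels[sac] <- spec$sac_label_id
  if (jitter)
    labels <- jitter_labels(labels, seed = seed, prob = jitter_prob)
  truth <- do.call(rbind, lapply(spec$tubules, function(tb) {
    ax <- tubule_axis(tb)
    data.frame(label_id = tb$label_id, name = tb$name,
               alpha_v = tb$alpha_v, alpha_h = tb$alpha_h,
               length = tb$length, radius = tb$radius,
               total_length = tb$length + 2 * tb$radius,
               volume = capsule_volume(tb$length, tb$radius),
               origin_x = tb$origin[1], origin_y = tb$origin[2],
               origin_z = tb$origin[3],
               axis_x = ax[1], axis_y = ax[2], axis_z = ax[3])
  }))
  tab <- data.frame(
    label_id = c(vapply(spec$tubules, `[[`, integer(1), "label_id"),
                 spec$sac_label_id),
    name = c(vapply(spec$tubules, `[[`, character(1), "name"),
             "rostral_sac"))
  list(volume = labeled_volume(labels, spec$voxel_size, label_table = tab),
       truth = truth)
}

shift3 <- function(x, s) {
  # logical array shifted by s (3-vector), FALSE-padded
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (s[a] >= 0) {
      if (s[a] >= d[a]) return(out)
      src[[a]] <- 1:(d[a] - s[a]); dst[[a]] <- (1 + s[a]):d[a]
    } else {
      if (-s[a] >= d[a]) return(out)
      src[[a]] <- (1 - s[a]):d[a]; dst[[a]] <- 1:(d[a] + s[a])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

neighbors6 <- function(mask) {
  out <- array(FALSE, dim(mask))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    out <- out | shift3(mask, s)
  out
}

#' Seeded one-voxel boundary jitter of a label map
#'
#' Emulates segmentation noise: for each label, boundary voxels may be
#' eroded and adjacent background voxels dilated, each with probability
#' `prob`. Labels stay pairwise disjoint.
#'
#' @param labels 3D integer array.
#' @param seed Integer seed.
#' @param prob Per-voxel flip probability.
#' @return Perturbed integer array.
#' @export
jitter_labels <- function(labels, seed = 1L, prob = 0.5) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(seed))
  out <- labels
  for (l in sort(setdiff(unique(as.integer(labels)), 0L))) {
    mask <- out == l
    bg <- out == 0L
    grow <- bg & neighbors6(mask)
    erode <- mask & neighbors6(!mask & TRUE)  # touches any non-l voxel
    gi <- which(grow)
    ei <- which(erode)
    if (length(gi))
      out[gi[stats::runif(length(gi)) < prob]] <- l
    if (length(ei))
      out[ei[stats::runif(length(ei)) < prob]] <- 0L
  }
  out
}
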