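#' Three-torus overlap region of balanced sensitivity
#'
#' Voxelises the intersection of the antennas' solid iso-gain tori: the
#' region of space where all pairs respond with at least the gain their
#' torus represents, i.e. the balanced maximum-sensitivity zone of the
#' whole array. The intersection is computed by point membership
#' ([torus_contains()]) on a regular grid covering the union of the
#' tori's bounding boxes, processed slab by slab to bound memory.
#'
#' @param tori List of [torus()] objects (three for the full array; any
#'   number `>= 1` is accepted).
#' @param voxel_size Grid spacing in mm (default 2).
#' @param mouth_landmark Optional 3-vector, mm: reports the distance from
#'   the overlap centroid to this point.
#' @param bbox Optional 2 x 3 matrix `rbind(lo, hi)` of grid bounds, mm.
#'   Must cover every torus's bounding box (error otherwise).
#' @param clip_plane Optional list `list(point = , normal = )` restricting
#'   the region to the half-space `(p - point) . normal >= 0`. The pure
#'   three-torus intersection also contains an antipodal lobe behind the
#'   array, inside the animal's own head where no ambient water exists;
#'   clipping to the exterior half-space keeps the physically meaningful
#'   detection zone. Default `NULL` (no clipping).
#' @return Object of class `overlap_region`: `mask`, `origin`,
#'   `voxel_size`, `n_voxels`, `volume` (mm^3), `centroid` (mm; `NA` when
#'   empty), `equivalent_sphere_radius` (mm), `distance_to_mouth` (mm or
#'   `NA`), `empty` flag. An empty intersection is a valid result, not an
#'   error.
#' @export
overlap_region <- function(tori, voxel_size = 2, mouth_landmark = NULL,
                           bbox = NULL, clip_plane = NULL) {
  stopifnot(is.list(tori), length(tori) >= 1L,
            all(vapply(tori, inherits, logical(1), "torus")),
            voxel_size > 0)
  if (!is.null(clip_plane)) {
    stopifnot(is.list(clip_plane),
              all(c("point", "normal") %in% names(clip_plane)))
    cp <- as.numeric(clip_plane$point)
    cn <- as.numeric(clip_plane$normal)
    cn <- cn / sqrt(sum(cn^2))
  }
  need <- torus_bbox(tori)
  if (is.null(bbox)) {
    bbox <- need
  } else {
    bbox <- as.matrix(bbox)
    stopifnot(all(dim(bbox) == c(2L, 3L)))
    if (any(bbox[1, ] > need[1, ]) || any(bbox[2, ] < need[2, ]))
      stop("grid bbox does not cover the torus bounding boxes")
  }
  origin <- bbox[1, ]
  dims <- pmax(1L, as.integer(ceiling((bbox[2, ] - bbox[1, ]) / voxel_size)))
  mask <- array(FALSE, dims)
  ij <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2])))
  xy <- sweep((ij - 0.5) * voxel_size, 2L, origin[1:2], "+")
  for (k in seq_len(dims[3])) {
    pts <- cbind(xy, origin[3] + (k - 0.5) * voxel_size)
    inside <- if (is.null(clip_plane)) rep(TRUE, nrow(pts)) else
      drop(sweep(pts, 2L, cp) %*% cn) >= 0
    for (t in tori) {
      if (!any(inside)) break
      inside[inside] <- torus_contains(pts[inside, , drop = FALSE], t)
    }
    mask[, , k] <- inside
  }
  summarize_overlap(mask, origin, voxel_size, mouth_landmark)
}

torus_bbox <- function(tori) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (t in tori) {
    ext <- t$R + t$b
    lo <- pmin(lo, t$center - ext)
    hi <- pmax(hi, t$center + ext)
  }
  rbind(lo, hi)
}

summarize_overlap <- function(mask, origin, voxel_size, mouth_landmark) {
  n <- sum(mask)
  vol <- n * voxel_size^3
  if (n > 0L) {
    idx <- which(mask, arr.ind = TRUE)
    ctr <- origin + colMeans((idx - 0.5) * voxel_size)
    names(ctr) <- c("x", "y", "z")
  } else {
    ctr <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  }
  structure(
    list(mask = mask, origin = origin, voxel_size = voxel_size,
         n_voxels = n, volume = vol, centroid = ctr,
         equivalent_sphere_radius = (3 * vol / (4 * pi))^(1 / 3),
         distance_to_mouth = if (!is.null(mouth_landmark) && n > 0L)
           sqrt(sum((ctr - mouth_landmark)^2)) else NA_real_,
         empty = n == 0L),
    class = "overlap_region")
}

#' @export
print.overlap_region <- function(x, ...) {
  if (x$empty) {
    cat("overlap_region: empty (volume 0)\n")
  } else {
    cat(sprintf(
      "overlap_region: %.0f mm^3 (%d voxels at %g mm), centroid (%.1f, %.1f, %.1f) mm\n",
      x$volume, x$n_voxels, x$voxel_size,
      x$centroid[1], x$centroid[2], x$centroid[3]))
    cat(sprintf("  equivalent sphere radius %.1f mm",
                x$equivalent_sphere_radius))
    if (!is.na(x$distance_to_mouth))
      cat(sprintf(", %.1f mm from the mouth landmark", x$distance_to_mouth))
    cat("\n")
  }
  invisible(x)
}

#' Sweep the gain band and track the overlap region
#'
#' Each antenna's torus is a thickened iso-gain shell: its core ring
#' (major radius `R = a + b`) marks where the target gain is met, and its
#' tube radius `b` the accepted band around it. Raising the detector's
#' accepted gain band corresponds to growing the tube radius while the
#' core ring stays put, i.e. to a family of nested tori about the same
#' ring (`b -> s b`, `a -> max(0, R - s b)`). Because the tori of larger
#' scale contain those of smaller scale, the overlap volume is
#' non-decreasing by set inclusion, while its location — anchored to the
#' ring crossing — should barely move; the sweep records both.
#'
#' @param antennas List of [antenna_pair()] objects.
#' @param scales Increasing positive scale factors (at least 2) applied
#'   to the tube radius.
#' @param a,b Base torus hole and tube radii, mm (shared by all antennas).
#' @param voxel_size Overlap grid spacing, mm.
#' @param mouth_landmark Optional 3-vector, mm.
#' @param clip_plane Optional exterior half-space (see
#'   [overlap_region()]), applied at every scale.
#' @return `data.frame`: one row per scale with `scale`, `volume`,
#'   `n_voxels`, `centroid_*`, `equivalent_sphere_radius`,
#'   `centroid_drift` (mm from the previous nonempty scale; `NA` for the
#'   first). Scales with empty overlap keep their volume-0 row.
#' @export
gain_sweep <- function(antennas, scales, a, b, voxel_size = 2,
                       mouth_landmark = NULL, clip_plane = NULL) {
  stopifnot(length(scales) >= 2L, all(scales > 0), !is.unsorted(scales))
  R <- a + b
  prev_ctr <- NULL
  rows <- lapply(scales, function(s) {
    tori <- lapply(antennas, function(ant)
      torus(ant$center, ant$axis, max(0, R - s * b), s * b))
    ov <- overlap_region(tori, voxel_size = voxel_size,
                         mouth_landmark = mouth_landmark,
                         clip_plane = clip_plane)
    drift <- if (!ov$empty && !is.null(prev_ctr))
      sqrt(sum((ov$centroid - prev_ctr)^2)) else NA_real_
    if (!ov$empty) prev_ctr <<- ov$centroid
    data.frame(scale = s, volume = ov$volume, n_voxels = ov$n_voxels,
               centroid_x = ov$centroid[["x"]],
               centroid_y = ov$centroid[["y"]],
               centroid_z = ov$centroid[["z"]],
               equivalent_sphere_radius = ov$equivalent_sphere_radius,
               centroid_drift = drift)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check the overlap centroid against a behavioural strike range
#'
#' Feeding strikes of drift-hunting coelacanths are initiated when prey
#' sits roughly 10-20 cm in front of the snout; a balanced-sensitivity
#' region consistent with that behaviour should have its centroid within
#' that distance band from the snout landmark (closed interval).
#'
#' @param overlap An [overlap_region()] (must be nonempty).
#' @param snout_landmark 3-vector, mm.
#' @param range_mm Closed interval, mm; default `c(100, 200)`.
#' @return List: `in_range` (logical), `distance` (mm), `range_mm`.
#' @export
calibrate_strike_range <- function(overlap, snout_landmark,
                                   range_mm = c(100, 200)) {
  stopifnot(inherits(overlap, "overlap_region"),
            length(snout_landmark) == 3L, length(range_mm) == 2L)
  if (overlap$empty)
    stop("overlap region is empty: no centroid to calibrate")
  d <- sqrt(sum((overlap$centroid - snout_landmark)^2))
  list(in_range = d >= range_mm[1] && d <= range_mm[2],
       distance = d, range_mm = range_mm)
}
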