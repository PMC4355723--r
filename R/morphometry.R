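#' Volume of one label, mm^3
#'
#' Voxel count times voxel volume.
#'
#' @param vol A [labeled_volume()].
#' @param label_id Label to measure (must be present).
#' @return Volume in mm^3.
#' @export
label_volume <- function(vol, label_id) {
  stopifnot(inherits(vol, "labeled_volume"))
  n <- sum(vol$labels == label_id)
  if (n == 0L)
    stop("label ", label_id, " not present in volume")
  n * voxel_volume(vol$voxel_size)
}

#' Centroid of one label, mm
#' @inheritParams label_volume
#' @return 3-vector, mm.
#' @export
label_centroid <- function(vol, label_id) {
  idx <- label_indices(vol, label_id)
  colMeans(voxel_centers(idx, vol$voxel_size))
}

#' Second-moment (inertia) tensor of a weighted volume
#'
#' The intensity-weighted second-moment matrix about the intensity
#' centroid, `M_jk = sum w(x) (x_j - c_j)(x_k - c_k) / sum w(x)`, in mm^2.
#' Its largest-eigenvalue eigenvector is the elongation (principal) axis;
#' the classical rotational inertia tensor `tr(M) I - M` has the same
#' eigenvectors with the eigenvalue order reversed.
#'
#' @param x 3D numeric or logical array of non-negative weights (a label
#'   mask, or a smoothed label field).
#' @param voxel_size Scalar or length-3 voxel size, mm.
#' @return 3x3 symmetric positive semi-definite matrix of class
#'   `inertia_tensor`, with attributes `centroid` (mm) and `weight`.
#' @export
inertia_tensor <- function(x, voxel_size) {
  stopifnot(length(dim(x)) == 3L)
  w <- as.numeric(x)
  keep <- which(w > 0)
  if (length(keep) == 0L)
    stop("empty volume: inertia tensor undefined")
  w <- w[keep]
  pts <- voxel_centers(arrayInd(keep, dim(x)), voxel_size)
  wsum <- sum(w)
  ctr <- colSums(pts * w) / wsum
  rel <- sweep(pts, 2L, ctr)
  M <- crossprod(rel * sqrt(w)) / wsum
  M <- (M + t(M)) / 2
  dimnames(M) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(M, centroid = ctr, weight = wsum, class = "inertia_tensor")
}

#' Principal (elongation) axis from an inertia tensor
#'
#' Unit eigenvector of the largest eigenvalue of the second-moment matrix,
#' i.e. the direction of maximal spatial extent. Requires a clear spectral
#' gap: near-spherical labels have no meaningful principal axis.
#'
#' @param tensor An [inertia_tensor()] (or any symmetric 3x3 matrix).
#' @param gap_tol Minimum relative gap `(e1 - e2) / e1` between the two
#'   largest eigenvalues.
#' @return Unit 3-vector (sign canonicalised: largest-magnitude component
#'   positive; see [orient_axis()] for anatomical orientation).
#' @export
principal_axis <- function(tensor, gap_tol = 1e-9) {
  M <- unclass(tensor)
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)))
  e <- eigen(M, symmetric = TRUE)
  if (e$values[1] <= 0)
    stop("tensor is not positive: no elongation axis")
  if ((e$values[1] - e$values[2]) / e$values[1] <= gap_tol)
    stop("degenerate spectrum: label is not tubular ",
         "(no unique elongation axis)")
  v <- e$vectors[, 1]
  j <- which.max(abs(v))
  if (v[j] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Orient an axis from the proximal toward the distal end
#'
#' Flips the sign of `axis` so that it points from the end of the label
#' nearest `reference` (e.g. the rostral-sac centroid) toward the far
#' (pore) end.
#'
#' @param axis Unit 3-vector (sign-ambiguous principal axis).
#' @param mask Logical or numeric 3D array supporting the label.
#' @param voxel_size Scalar or length-3 voxel size, mm.
#' @param reference 3-vector, mm: the proximal anchor point.
#' @return Unit 3-vector, possibly sign-flipped.
#' @export
orient_axis <- function(axis, mask, voxel_size, reference) {
  keep <- which(as.logical(mask != 0))
  if (length(keep) == 0L) stop("empty mask")
  pts <- voxel_centers(arrayInd(keep, dim(mask)), voxel_size)
  proj <- drop(pts %*% axis)
  lo_end <- pts[which.min(proj), ]
  hi_end <- pts[which.max(proj), ]
  d_lo <- sum((lo_end - reference)^2)
  d_hi <- sum((hi_end - reference)^2)
  if (d_hi < d_lo) -axis else axis
}

#' Tubule length along its principal axis
#'
#' Extent of the voxel-centre projections onto the axis, plus one voxel
#' size to account for the two boundary half-voxels.
#'
#' @param mask Logical or numeric 3D array supporting the label.
#' @param axis Unit 3-vector.
#' @param voxel_size Scalar or length-3 voxel size, mm.
#' @return Length in mm.
#' @export
tubule_length <- function(mask, axis, voxel_size) {
  keep <- which(as.logical(mask != 0))
  if (length(keep) == 0L) stop("empty mask")
  pts <- voxel_centers(arrayInd(keep, dim(mask)), voxel_size)
  proj <- drop(pts %*% axis)
  diff(range(proj)) + mean(rep_len(as.numeric(voxel_size), 3L))
}

#' Left/right pair summary
#'
#' Mean and n-1 sample standard deviation of a bilateral pair of
#' measurements; for two values the SD equals `|L - R| / sqrt(2)`.
#'
#' @param left,right The two finite measurements.
#' @param structure Optional structure name.
#' @return One-row `data.frame`: `structure`, `left`, `right`, `mean`,
#'   `sd`.
#' @export
pair_summary <- function(left, right, structure = "") {
  stopifnot(is.finite(left), is.finite(right))
  data.frame(structure = structure, left = left, right = right,
             mean = (left + right) / 2,
             sd = stats::sd(c(left, right)))
}

#' Total volume of the organ's components
#'
#' @param volumes Numeric vector of component volumes (six tubules plus
#'   the medial cavity, or any subset).
#' @return Their sum, mm^3 (0 for an empty vector).
#' @export
total_volume <- function(volumes) {
  volumes <- as.numeric(volumes)
  stopifnot(all(is.finite(volumes)))
  sum(volumes)
}

crop_label <- function(vol, label_id, margin = 2L) {
  idx <- label_indices(vol, label_id)
  dims <- dim(vol$labels)
  lo <- pmax(1L, apply(idx, 2L, min) - margin)
  hi <- pmin(dims, apply(idx, 2L, max) + margin)
  sub <- vol$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vs <- rep_len(vol$voxel_size, 3L)
  list(mask = array(sub == label_id, dim = dim(sub)),
       offset = (lo - 1L) * vs)   # mm shift of the cropped frame
}

#' Per-tubule morphometry records
#'
#' For each tubule label: volume (voxel counting), optional SWD smoothing
#' of the label indicator, second-moment tensor, principal axis (oriented
#' from the sac-proximal toward the pore-distal end), orientation angles
#' and length. Negative side lobes of the band-limited smoothed field are
#' clamped to zero before the tensor is formed, so the moment weights stay
#' non-negative.
#'
#' @param vol A [labeled_volume()].
#' @param label_ids Tubule labels to measure; default: every label except
#'   `sac_label`.
#' @param sac_label Label of the rostral sac / medial cavity, used as the
#'   proximal reference for axis orientation. `NULL` to skip orientation
#'   (axes keep their canonical sign).
#' @param smoothing `"none"` (raw mask moments) or `"swd"` (moments of the
#'   smoothed field).
#' @param L,N SWD truncation orders when `smoothing = "swd"`.
#' @return `data.frame` with one row per tubule: `label_id`, `name`,
#'   `volume`, `length`, `centroid_*`, `axis_*`, `alpha_v`, `alpha_h`.
#' @export
tubule_morphometry <- function(vol, label_ids = NULL, sac_label = NULL,
                               smoothing = c("none", "swd"),
                               L = 7L, N = 7L) {
  stopifnot(inherits(vol, "labeled_volume"))
  smoothing <- match.arg(smoothing)
  present <- vol$label_table$label_id
  if (is.null(label_ids))
    label_ids <- setdiff(present, sac_label)
  sac_ctr <- if (!is.null(sac_label)) label_centroid(vol, sac_label)
  rows <- lapply(label_ids, function(lab) {
    cr <- crop_label(vol, lab)
    vs <- vol$voxel_size
    w <- if (smoothing == "swd") {
      pmax(swd_smooth(cr$mask, vs, L = L, N = N), 0)
    } else cr$mask
    M <- inertia_tensor(w, vs)
    ax <- principal_axis(M)
    ref_local <- if (!is.null(sac_ctr)) sac_ctr - cr$offset
    if (!is.null(ref_local))
      ax <- orient_axis(ax, cr$mask, vs, ref_local)
    ang <- tubule_angles(ax)
    ctr <- attr(inertia_tensor(cr$mask, vs), "centroid") + cr$offset
    nm <- vol$label_table$name[match(lab, vol$label_table$label_id)]
    data.frame(label_id = lab,
               name = if (is.na(nm)) as.character(lab) else nm,
               volume = label_volume(vol, lab),
               length = tubule_length(cr$mask, ax, vs),
               centroid_x = ctr[1], centroid_y = ctr[2],
               centroid_z = ctr[3],
               axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
               alpha_v = ang[["alpha_v"]], alpha_h = ang[["alpha_h"]])
  })
  do.call(rbind, rows)
}
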