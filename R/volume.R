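#' Labelled 3D volume
#'
#' A light container for an integer label map on a regular voxel grid:
#' a 3D integer array (`0` = background), a physical voxel size in mm
#' (scalar for isotropic grids, length-3 for anisotropic), an optional
#' label table naming each label, and the package's anatomical axis
#' convention (see [axis_convention()]).
#'
#' Voxel `(i, j, k)` has its centre at physical coordinate
#' `((i, j, k) - 0.5) * voxel_size` mm, so the grid's corner is at the
#' origin.
#'
#' @param labels 3D array of non-negative integers (0 = background).
#' @param voxel_size Voxel edge length(s) in mm; length 1 or 3, positive.
#' @param label_table Optional `data.frame` with columns `label_id`,
#'   `name`; defaults to unnamed entries for the labels present.
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size, label_table = NULL) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  voxel_size <- as.numeric(voxel_size)
  if (!length(voxel_size) %in% c(1L, 3L) || any(voxel_size <= 0))
    stop("voxel_size must be positive, length 1 or 3")
  present <- sort(setdiff(unique(as.integer(labels)), 0L))
  if (is.null(label_table)) {
    label_table <- data.frame(label_id = present,
                              name = as.character(present))
  } else {
    if (!all(c("label_id", "name") %in% names(label_table)))
      stop("label_table needs columns label_id and name")
    missing_ids <- setdiff(present, label_table$label_id)
    if (length(missing_ids))
      stop("labels present but not in label_table: ",
           paste(missing_ids, collapse = ", "))
  }
  structure(
    list(labels = labels,
         voxel_size = voxel_size,
         label_table = label_table,
         axis_convention = axis_convention()),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  vs <- if (length(x$voxel_size) == 1L) {
    sprintf("%g mm isotropic", x$voxel_size)
  } else {
    paste(sprintf("%g", x$voxel_size), collapse = " x ")
  }
  cat(sprintf("labeled_volume: %d x %d x %d voxels, %s\n",
              d[1], d[2], d[3], vs))
  cat(sprintf("  %d labels: %s\n", nrow(x$label_table),
              paste(x$label_table$name, collapse = ", ")))
  invisible(x)
}

#' Voxel volume of a grid in cubic mm
#' @param voxel_size Scalar or length-3 voxel size in mm.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(voxel_size) prod(rep_len(as.numeric(voxel_size), 3L))

#' Physical coordinates of voxel centres
#'
#' @param idx Integer matrix of voxel indices (n x 3, 1-based).
#' @param voxel_size Scalar or length-3 voxel size in mm.
#' @return n x 3 matrix of mm coordinates.
#' @keywords internal
voxel_centers <- function(idx, voxel_size) {
  vs <- rep_len(as.numeric(voxel_size), 3L)
  sweep(idx - 0.5, 2L, vs, "*")
}

#' Indices (n x 3) of voxels carrying a label
#' @keywords internal
label_indices <- function(vol, label_id) {
  stopifnot(inherits(vol, "labeled_volume"))
  w <- which(vol$labels == label_id, arr.ind = TRUE)
  if (nrow(w) == 0L)
    stop("label ", label_id, " not present in volume")
  w
}

#' Write a labelled volume to NIfTI
#'
#' Stores the integer label grid with the voxel size encoded in the NIfTI
#' pixdim/affine. Round-trips through [read_labeled_volume()] losslessly.
#'
#' @param vol A [labeled_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  img <- RNifti::asNifti(array(as.integer(vol$labels), dim = dim(vol$labels)))
  RNifti::pixdim(img) <- rep_len(vol$voxel_size, 3L)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Read a labelled volume from NIfTI
#'
#' The file must contain integer-valued data; any non-integer voxel value
#' is an error (label maps are categorical). Anisotropic voxels are
#' accepted, in which case `voxel_size` is a 3-vector.
#'
#' @param path NIfTI file path.
#' @param label_table Optional label table (see [labeled_volume()]).
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(path, label_table = NULL) {
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  if (length(dim(dat)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(dat)), " dims")
  if (anyNA(dat) || any(abs(dat - round(dat)) > 0))
    stop("NIfTI data are not integer-valued; not a label map")
  vs <- RNifti::pixdim(img)[1:3]
  if (anyNA(vs) || any(vs <= 0))
    stop("NIfTI pixdim does not encode a positive voxel size")
  if (max(vs) - min(vs) < 1e-9) vs <- vs[1]
  labeled_volume(array(as.integer(round(dat)), dim = dim(dat)),
                 voxel_size = vs, label_table = label_table)
}
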