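#' Anatomical axis convention
#'
#' All 3D coordinates in this package use a fixed mapping of grid axes to
#' anatomical axes: axis 1 (x) is the head-tail axis with positive values
#' anterior, axis 2 (y) is the left-right axis with positive values toward
#' the specimen's left, and axis 3 (z) is the dorsoventral axis with
#' positive values dorsal.
#'
#' A tubule orientation is described by two angles:
#' \describe{
#'   \item{`alpha_v`}{inclination of the tubule axis relative to the
#'     head-tail axis, in degrees, in `[0, 180]`. `alpha_v = 0` points
#'     straight anterior.}
#'   \item{`alpha_h`}{rotation of the axis within the plane orthogonal to
#'     the head-tail axis, in degrees, in `(-180, 180]`, measured from the
#'     dorsal direction and positive rotating toward the specimen's left.}
#' }
#'
#' Under this convention the unit axis vector is
#' `v = (cos(alpha_v), sin(alpha_v) sin(alpha_h), sin(alpha_v) cos(alpha_h))`.
#'
#' @return A named character vector describing the three axes.
#' @export
axis_convention <- function() {
  c(x = "head-tail (+anterior)",
    y = "left-right (+left)",
    z = "dorsoventral (+dorsal)")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Convert orientation angles to a unit axis vector
#'
#' Inverse of [tubule_angles()]. Vectorised over angle pairs.
#'
#' @param alpha_v Inclination relative to the head-tail axis, degrees,
#'   in `[0, 180]`.
#' @param alpha_h Rotation in the plane orthogonal to the head-tail axis,
#'   degrees, in `(-180, 180]` (see [axis_convention()]). Degenerate at the
#'   poles (`alpha_v` of 0 or 180), where any value gives the same vector.
#' @return A unit 3-vector for scalar input, otherwise an `n x 3` matrix
#'   with one unit row per angle pair.
#' @examples
#' angles_to_unit_vector(0, 0)        # straight anterior
#' angles_to_unit_vector(90, 0)       # straight dorsal
#' angles_to_unit_vector(40.05, -100.68)
#' @export
angles_to_unit_vector <- function(alpha_v, alpha_h) {
  stopifnot(is.numeric(alpha_v), is.numeric(alpha_h))
  n <- max(length(alpha_v), length(alpha_h))
  alpha_v <- rep_len(alpha_v, n)
  alpha_h <- rep_len(alpha_h, n)
  if (any(alpha_v < 0 | alpha_v > 180))
    stop("alpha_v must lie in [0, 180] degrees")
  if (any(alpha_h <= -180 | alpha_h > 180))
    stop("alpha_h must lie in (-180, 180] degrees")
  av <- deg2rad(alpha_v)
  ah <- deg2rad(alpha_h)
  v <- cbind(x = cos(av), y = sin(av) * sin(ah), z = sin(av) * cos(ah))
  if (n == 1L) drop(v) else v
}

#' Extract orientation angles from a unit axis vector
#'
#' Inverse of [angles_to_unit_vector()] under the package axis convention.
#' At the poles (axis along the head-tail axis) `alpha_h` is undefined and
#' reported as 0 by convention.
#'
#' @param axis A unit 3-vector (checked to within `tol` of unit length).
#' @param tol Tolerance on `|axis| - 1`.
#' @return Named numeric vector `c(alpha_v = , alpha_h = )` in degrees.
#' @export
tubule_angles <- function(axis, tol = 1e-6) {
  axis <- as.numeric(axis)
  if (length(axis) != 3L || anyNA(axis))
    stop("axis must be a numeric 3-vector")
  if (abs(sqrt(sum(axis^2)) - 1) > tol)
    stop("axis must be a unit vector (|axis| = 1 within tol)")
  alpha_v <- rad2deg(acos(min(1, max(-1, axis[1]))))
  if (hypot2(axis[2], axis[3]) < 1e-12) {
    alpha_h <- 0
  } else {
    alpha_h <- rad2deg(atan2(axis[2], axis[3]))
    if (alpha_h <= -180) alpha_h <- alpha_h + 360
  }
  c(alpha_v = alpha_v, alpha_h = alpha_h)
}

hypot2 <- function(a, b) sqrt(a * a + b * b)

#' Range of a set of angles
#'
#' Linear mode is the plain `max - min`. Circular mode treats the values as
#' points on the circle and returns `360 -` the largest gap between
#' consecutive sorted angles, i.e. the smallest arc containing all values.
#'
#' @param values Angles in degrees.
#' @param circular Use the circular definition? Default `FALSE` (linear).
#' @return Range in degrees.
#' @examples
#' angle_range(c(-170, 170))                  # 340
#' angle_range(c(-170, 170), circular = TRUE) # 20
#' @export
angle_range <- function(values, circular = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("values must be a nonempty numeric vector of angles")
  if (!circular)
    return(max(values) - min(values))
  if (length(values) == 1L)
    return(0)
  th <- sort(((values %% 360) + 360) %% 360)
  gaps <- diff(c(th, th[1] + 360))
  360 - max(gaps)
}
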