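#' Dipole antenna for a left/right tubule pair
#'
#' Each bilateral tubule pair acts as one "rabbit ears" dipole receiver:
#' a centre point between the two tubules and a single dipole axis. Canal
#' voltage sensitivity follows the cosine of the angle between the local
#' electric field and the canal axis, so the pair's spatial gain pattern
#' is maximal broadside to the dipole axis and zero along it, with
#' iso-gain surfaces shaped like ring tori (see [dipole_gain()]).
#'
#' @param name Pair name (e.g. `"anterior"`).
#' @param center 3-vector, mm.
#' @param axis Unit 3-vector (dipole axis; sign irrelevant to the gain).
#' @param members Optional list of the two member tubule records.
#' @return Object of class `antenna_pair`.
#' @export
antenna_pair <- function(name, center, axis, members = NULL) {
  center <- as.numeric(center)
  axis <- as.numeric(axis)
  stopifnot(length(center) == 3L, all(is.finite(center)),
            length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6)
    stop("axis must be a unit vector")
  structure(list(name = as.character(name), center = center,
                 axis = axis / nrm, members = members),
            class = "antenna_pair")
}

#' @export
print.antenna_pair <- function(x, ...) {
  cat(sprintf("antenna_pair '%s': center (%.1f, %.1f, %.1f) mm, axis (%.3f, %.3f, %.3f)\n",
              x$name, x$center[1], x$center[2], x$center[3],
              x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Build the dipole antenna of a tubule pair
#'
#' The centre is the midpoint of the two tubule centroids. The dipole
#' axis comes from one of two strategies: `"bisector"` (default), the
#' normalised sum of the two oriented tubule principal axes (the
#' direction bisecting the "rabbit ears" V), or `"baseline"`, the unit
#' vector between the two distal (pore-end) tips.
#'
#' @param left,right One-row tubule records (rows of
#'   [tubule_morphometry()] output) for the left and right member.
#' @param strategy `"bisector"` or `"baseline"`.
#' @param name Pair name; default derived from the left record.
#' @return An [antenna_pair()].
#' @export
pair_dipole <- function(left, right, strategy = c("bisector", "baseline"),
                        name = NULL) {
  strategy <- match.arg(strategy)
  get3 <- function(rec, stem)
    c(rec[[paste0(stem, "_x")]], rec[[paste0(stem, "_y")]],
      rec[[paste0(stem, "_z")]])
  cl <- get3(left, "centroid"); cr <- get3(right, "centroid")
  al <- get3(left, "axis");     ar <- get3(right, "axis")
  center <- (cl + cr) / 2
  if (strategy == "bisector") {
    s <- al + ar
    nrm <- sqrt(sum(s^2))
    if (nrm < 1e-6)
      stop("tubule axes are anti-parallel: the bisector is undefined; ",
           "use strategy = \"baseline\"")
    axis <- s / nrm
  } else {
    tl <- cl + (left$length / 2) * al
    tr <- cr + (right$length / 2) * ar
    d <- tl - tr
    nrm <- sqrt(sum(d^2))
    if (nrm < 1e-9)
      stop("distal endpoints coincide: baseline axis undefined")
    axis <- d / nrm
  }
  if (is.null(name))
    name <- sub("_[LR]$", "", as.character(left$name))
  antenna_pair(name, center, axis,
               members = list(left = left, right = right))
}

#' Short-dipole gain pattern
#'
#' `g = sin^2(theta) / r^2`, with `theta` the angle between the point's
#' direction from the antenna centre and the dipole axis, and `r` the
#' distance in mm. This is the canonical short-dipole power pattern:
#' maximal broadside, zero along the axis, rotationally symmetric, and
#' with superlevel sets `{g >= c}` that are solid tori of revolution
#' (tube radius `1 / (2 sqrt(c))`).
#'
#' @param points 3-vector or n x 3 matrix, mm.
#' @param antenna An [antenna_pair()].
#' @return Non-negative gain value(s). Error for a point at the centre.
#' @export
dipole_gain <- function(points, antenna) {
  stopifnot(inherits(antenna, "antenna_pair"))
  p <- if (is.null(dim(points))) matrix(points, 1L, 3L) else
    as.matrix(points)
  stopifnot(ncol(p) == 3L)
  u <- sweep(p, 2L, antenna$center)
  r2 <- rowSums(u^2)
  if (any(r2 == 0))
    stop("gain is undefined at the antenna centre")
  ca2 <- drop(u %*% antenna$axis)^2 / r2
  g <- pmax(0, 1 - ca2) / r2
  if (is.null(dim(points))) g[1] else g
}

#' Ring torus
#'
#' A solid ring torus around `axis` through `center`: hole radius `a`
#' (radius of the internal centre area), tube radius `b` (radius of the
#' external ring), major radius `R = a + b` (distance from the centre to
#' the tube's core circle). `a = 0` gives a horn torus, the exact shape
#' of a short-dipole iso-gain region.
#'
#' @param center 3-vector, mm.
#' @param axis Unit 3-vector.
#' @param a Hole radius, mm, `>= 0`.
#' @param b Tube radius, mm, `> 0`.
#' @return Object of class `torus`.
#' @export
torus <- function(center, axis, a, b) {
  center <- as.numeric(center); axis <- as.numeric(axis)
  stopifnot(length(center) == 3L, length(axis) == 3L,
            is.finite(a), is.finite(b), a >= 0, b > 0)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm - 1) > 1e-6) stop("axis must be a unit vector")
  structure(list(center = center, axis = axis / nrm, a = a, b = b,
                 R = a + b),
            class = "torus")
}

#' @export
print.torus <- function(x, ...) {
  cat(sprintf("torus: a = %.2f, b = %.2f (R = %.2f) mm at (%.1f, %.1f, %.1f)\n",
              x$a, x$b, x$R, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Scale a torus about its centre
#' @param t A [torus()].
#' @param s Positive scale factor applied to `a` and `b` jointly.
#' @return A [torus()].
#' @export
scale_torus <- function(t, s) {
  stopifnot(inherits(t, "torus"), s > 0)
  torus(t$center, t$axis, t$a * s, t$b * s)
}

#' Analytic solid-torus volume, `2 pi^2 R b^2`
#' @param t A [torus()].
#' @return Volume in mm^3.
#' @export
torus_volume <- function(t) {
  stopifnot(inherits(t, "torus"))
  2 * pi^2 * t$R * t$b^2
}

#' Point membership in a solid torus
#'
#' In torus-local cylindrical coordinates (`z` along the axis, `rho` the
#' distance from it), the point is inside iff
#' `(rho - R)^2 + z^2 <= b^2`.
#'
#' @param points 3-vector or n x 3 matrix, mm.
#' @param t A [torus()].
#' @return Logical vector.
#' @export
torus_contains <- function(points, t) {
  stopifnot(inherits(t, "torus"))
  p <- if (is.null(dim(points))) matrix(points, 1L, 3L) else
    as.matrix(points)
  u <- sweep(p, 2L, t$center)
  z <- drop(u %*% t$axis)
  rho2 <- pmax(0, rowSums(u^2) - z^2)
  (sqrt(rho2) - t$R)^2 + z^2 <= t$b^2
}

#' Sampled points on a dipole iso-gain surface
#'
#' Samples the gain on a regular grid around the antenna, locates all
#' grid-edge crossings of `g = level`, and polishes each crossing along
#' its edge by bisection, so every returned point satisfies the level-set
#' equation to near machine precision. Points inside the near-field
#' exclusion radius `r_min` are dropped: the point-dipole pattern is not
#' meaningful arbitrarily close to the antenna, and the iso-surface
#' pinches into the centre there.
#'
#' @param antenna An [antenna_pair()].
#' @param level Gain level, `> 0`.
#' @param n Grid points per axis.
#' @param r_min Near-field exclusion radius, mm; default
#'   `2 sqrt(h b)` with `h` the grid spacing and `b = 1 / (2 sqrt(level))`
#'   the tube radius at this level.
#' @return n x 3 matrix of surface points (mm), with attribute `level`.
#' @export
gain_isosurface_points <- function(antenna, level, n = 64L, r_min = NULL) {
  stopifnot(inherits(antenna, "antenna_pair"), level > 0, n >= 8L)
  b_lvl <- 1 / (2 * sqrt(level))
  half <- 2.15 * b_lvl
  h <- 2 * half / (n - 1)
  if (is.null(r_min)) r_min <- 2 * sqrt(h * b_lvl)
  ax <- seq(-half, half, length.out = n)
  g <- function(p) dipole_gain(p, antenna)
  grid1 <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pts <- sweep(grid1, 2L, antenna$center, "+")
  # avoid the exact centre (gain undefined there)
  r0 <- sqrt(rowSums(sweep(pts, 2L, antenna$center)^2))
  pts[r0 < 1e-9, 1] <- pts[r0 < 1e-9, 1] + h * 1e-3
  gv <- array(g(pts) - level, dim = c(n, n, n))
  coord <- lapply(1:3, function(d) array(pts[, d], dim = c(n, n, n)))
  lo_list <- hi_list <- list()
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    gp <- aperm(gv, perm)
    f1 <- gp[1:(n - 1), , , drop = FALSE]
    f2 <- gp[2:n, , , drop = FALSE]
    cross <- which(f1 * f2 < 0)
    if (!length(cross)) next
    p1 <- matrix(0, length(cross), 3L); p2 <- p1
    for (d in 1:3) {
      cp <- aperm(coord[[d]], perm)
      p1[, d] <- cp[1:(n - 1), , , drop = FALSE][cross]
      p2[, d] <- cp[2:n, , , drop = FALSE][cross]
    }
    sw <- f1[cross] > 0  # ensure p1 below the level, p2 above
    tmp <- p1[sw, , drop = FALSE]; p1[sw, ] <- p2[sw, , drop = FALSE]
    p2[sw, ] <- tmp
    lo_list[[a]] <- p1; hi_list[[a]] <- p2
  }
  lo <- do.call(rbind, lo_list); hi <- do.call(rbind, hi_list)
  if (is.null(lo) || nrow(lo) == 0L)
    stop("empty isosurface at this gain level")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    below <- g(mid) < level
    lo[below, ] <- mid[below, , drop = FALSE]
    hi[!below, ] <- mid[!below, , drop = FALSE]
  }
  out <- (lo + hi) / 2
  r <- sqrt(rowSums(sweep(out, 2L, antenna$center)^2))
  out <- out[r >= r_min, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("empty isosurface outside the near-field exclusion radius")
  attr(out, "level") <- level
  out
}

#' Fit a ring torus to an antenna's iso-gain surface
#'
#' Extracts the `g = gain_level` surface of the antenna's dipole pattern
#' and fits a circle to its cross-section in cylindrical coordinates
#' about the antenna axis (algebraic least squares), giving the hole
#' radius `a`, tube radius `b` and an axial centre offset. For the ideal
#' short dipole the iso-gain region is exactly a horn torus
#' (`a = 0`, `b = 1 / (2 sqrt(level))`).
#'
#' @param antenna An [antenna_pair()].
#' @param gain_level Gain level, `> 0`.
#' @param n Sampling grid points per axis.
#' @return A [torus()] with attributes `fit_rms` (RMS radial residual,
#'   mm) and `raw_a` (the unclamped fitted hole radius).
#' @export
gain_to_torus <- function(antenna, gain_level, n = 64L) {
  pts <- gain_isosurface_points(antenna, gain_level, n = n)
  fit <- fit_torus_to_points(pts, antenna$center, antenna$axis)
  fit
}

#' Least-squares ring torus through a point cloud
#'
#' Fits, about a fixed axis, the cross-section circle
#' `(rho - R)^2 + (z - z0)^2 = b^2` to the points' cylindrical
#' coordinates (Kasa algebraic fit), then reports the torus with
#' `a = max(0, R - b)` and centre shifted by `z0` along the axis.
#'
#' @param points n x 3 matrix, mm.
#' @param center 3-vector: axis anchor point.
#' @param axis Unit 3-vector.
#' @return A [torus()] with attributes `fit_rms` and `raw_a`.
#' @export
fit_torus_to_points <- function(points, center, axis) {
  p <- as.matrix(points)
  stopifnot(ncol(p) == 3L, nrow(p) >= 4L)
  axis <- axis / sqrt(sum(axis^2))
  u <- sweep(p, 2L, as.numeric(center))
  z <- drop(u %*% axis)
  rho <- sqrt(pmax(0, rowSums(u^2) - z^2))
  X <- cbind(2 * rho, 2 * z, 1)
  y <- rho^2 + z^2
  beta <- qr.solve(X, y)
  R <- beta[1]; z0 <- beta[2]
  b2 <- beta[3] + R^2 + z0^2
  if (b2 <= 0 || R <= 0)
    stop("torus fit failed: degenerate point cloud")
  b <- sqrt(b2)
  rms <- sqrt(mean((sqrt((rho - R)^2 + (z - z0)^2) - b)^2))
  raw_a <- R - b
  out <- torus(as.numeric(center) + z0 * axis, axis,
               a = max(0, raw_a), b = b)
  attr(out, "fit_rms") <- rms
  attr(out, "raw_a") <- raw_a
  out
}

#' Voxelised superlevel set of a dipole gain pattern
#'
#' Boolean mask of `{g >= level, r >= r_min}` on a regular grid covering
#' the pattern's torus. The near-field ball `r < r_min` is excluded (see
#' [gain_isosurface_points()]); this keeps the central pinch of the horn
#' torus open so the region has honest toroidal topology.
#'
#' @param antenna An [antenna_pair()].
#' @param level Gain level.
#' @param voxel_size Grid spacing, mm.
#' @param r_min Near-field exclusion radius; default `2 sqrt(h b)`.
#' @return List: `mask` (logical array), `origin` (mm coordinate of the
#'   grid corner), `voxel_size`.
#' @export
gain_region_mask <- function(antenna, level, voxel_size, r_min = NULL) {
  stopifnot(level > 0, voxel_size > 0)
  b_lvl <- 1 / (2 * sqrt(level))
  if (is.null(r_min)) r_min <- 2 * sqrt(voxel_size * b_lvl)
  half <- 2.1 * b_lvl
  origin <- antenna$center - half
  dims <- rep(ceiling(2 * half / voxel_size), 3L)
  mask <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    idx <- as.matrix(expand.grid(i = seq_len(dims[1]),
                                 j = seq_len(dims[2]), k = k))
    pts <- sweep((idx - 0.5) * voxel_size, 2L, origin, "+")
    u <- sweep(pts, 2L, antenna$center)
    r2 <- rowSums(u^2)
    ok <- r2 >= r_min^2
    g <- rep(0, nrow(pts))
    g[ok] <- dipole_gain(pts[ok, , drop = FALSE], antenna)
    mask[, , k] <- g >= level
  }
  list(mask = mask, origin = origin, voxel_size = voxel_size)
}
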