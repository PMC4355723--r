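#' Spherical Bessel function of the first kind
#'
#' `j_l(x) = sqrt(pi / (2x)) J_{l + 1/2}(x)`, with the series limit
#' `x^l / (2l + 1)!!` substituted near the origin for numerical safety.
#'
#' @param l Non-negative integer order.
#' @param x Numeric vector, `x >= 0`.
#' @return `j_l(x)`, same length as `x`.
#' @export
sph_bessel_j <- function(l, x) {
  stopifnot(l >= 0, l == round(l))
  x <- as.numeric(x)
  out <- numeric(length(x))
  tiny <- x < 1e-6
  if (any(!tiny)) {
    xs <- x[!tiny]
    out[!tiny] <- sqrt(pi / (2 * xs)) * besselJ(xs, l + 0.5)
  }
  if (any(tiny)) {
    # x^l / (2l+1)!! ; exact at x = 0
    dfact <- prod(seq(1, 2 * l + 1, by = 2))
    out[tiny] <- x[tiny]^l / dfact
  }
  out
}

.swd_cache <- new.env(parent = emptyenv())

#' Positive zeros of the spherical Bessel function j_l
#'
#' Found by bracketing sign changes of `J_{l+1/2}` on a fine scan and
#' polishing with [stats::uniroot()]; cached per `(l, n)`.
#'
#' @param l Non-negative integer order.
#' @param n Number of zeros wanted.
#' @return Numeric vector of the first `n` positive zeros, increasing.
#' @export
sph_bessel_zeros <- function(l, n) {
  stopifnot(l >= 0, l == round(l), n >= 1, n == round(n))
  key <- sprintf("l%d", l)
  z <- get0(key, envir = .swd_cache, ifnotfound = numeric(0))
  if (length(z) >= n) return(z[seq_len(n)])
  f <- function(x) besselJ(x, l + 0.5)
  lo <- if (length(z)) max(z) else max(l, 0.5)
  step <- 0.05
  while (length(z) < n) {
    xs <- seq(lo, lo + 20, by = step)
    fs <- f(xs)
    sgn <- which(fs[-1] * fs[-length(fs)] < 0)
    for (i in sgn) {
      r <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-13)$root
      z <- c(z, r)
      if (length(z) >= n) break
    }
    lo <- lo + 20
  }
  assign(key, z, envir = .swd_cache)
  z[seq_len(n)]
}

#' Real orthonormal spherical harmonics up to order L
#'
#' Evaluates the real spherical-harmonic basis at given directions using
#' stable normalised associated-Legendre recurrences. Columns are ordered
#' by `l` then `m = -l..l`, with negative `m` the sine terms and positive
#' `m` the cosine terms; the basis is orthonormal on the unit sphere.
#'
#' @param cos_theta Cosine of the polar angle (from the package z axis).
#' @param phi Azimuth, radians (`atan2(y, x)`).
#' @param L Maximum degree.
#' @return Matrix `length(cos_theta) x (L+1)^2` with attribute `index`
#'   (a `data.frame` of `l`, `m`).
#' @export
real_spherical_harmonics <- function(cos_theta, phi, L) {
  stopifnot(L >= 0, L == round(L))
  ct <- pmin(1, pmax(-1, as.numeric(cos_theta)))
  st <- sqrt(pmax(0, 1 - ct^2))
  n <- length(ct)
  # normalised associated Legendre P~_l^m, keyed "l.m"
  P <- vector("list", (L + 1) * (L + 2) / 2)
  pk <- function(l, m) l * (l + 1) / 2 + m + 1
  P[[pk(0, 0)]] <- rep(sqrt(1 / (4 * pi)), n)
  if (L >= 1) {
    for (m in 1:L)
      P[[pk(m, m)]] <- -sqrt((2 * m + 1) / (2 * m)) * st *
        P[[pk(m - 1, m - 1)]]
    for (m in 0:(L - 1))
      P[[pk(m + 1, m)]] <- sqrt(2 * m + 3) * ct * P[[pk(m, m)]]
    if (L >= 2) {
      for (m in 0:(L - 2)) {
        for (l in (m + 2):L) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          P[[pk(l, m)]] <- a * (ct * P[[pk(l - 1, m)]] -
                                  b * P[[pk(l - 2, m)]])
        }
      }
    }
  }
  nb <- (L + 1)^2
  Y <- matrix(0, n, nb)
  idx <- data.frame(l = integer(nb), m = integer(nb))
  col <- 0L
  sqrt2 <- sqrt(2)
  for (l in 0:L) {
    for (m in (-l):l) {
      col <- col + 1L
      idx$l[col] <- l; idx$m[col] <- m
      Y[, col] <- if (m == 0) P[[pk(l, 0)]]
        else if (m > 0) sqrt2 * P[[pk(l, m)]] * cos(m * phi)
        else sqrt2 * P[[pk(l, -m)]] * sin(-m * phi)
    }
  }
  attr(Y, "index") <- idx
  Y
}

swd_basis_matrix <- function(pts_rel, radius, L, N) {
  r <- sqrt(rowSums(pts_rel^2))
  ct <- ifelse(r > 0, pts_rel[, 3] / r, 1)
  phi <- atan2(pts_rel[, 2], pts_rel[, 1])
  Y <- real_spherical_harmonics(ct, phi, L)
  yidx <- attr(Y, "index")
  s <- pmin(1, r / radius)
  rad <- vector("list", L + 1)
  for (l in 0:L) {
    z <- sph_bessel_zeros(l, N)
    rad[[l + 1]] <- vapply(seq_len(N),
                           function(n) sph_bessel_j(l, z[n] * s),
                           numeric(length(s)))
  }
  nb <- (L + 1)^2 * N
  A <- matrix(0, nrow(pts_rel), nb)
  index <- data.frame(l = integer(nb), m = integer(nb), n = integer(nb))
  col <- 0L
  for (j in seq_len(ncol(Y))) {
    l <- yidx$l[j]
    for (n in seq_len(N)) {
      col <- col + 1L
      index$l[col] <- l; index$m[col] <- yidx$m[j]; index$n[col] <- n
      A[, col] <- Y[, j] * rad[[l + 1]][, n]
    }
  }
  attr(A, "index") <- index
  A
}

#' Spherical-wave decomposition of a volume
#'
#' Expands a (mask or intensity) volume, centred on its centroid and
#' scaled to its bounding sphere, in the basis of real spherical harmonics
#' `Y_lm` times spherical Bessel radial functions `j_l(z_ln r / R)`, where
#' `z_ln` is the n-th positive zero of `j_l` (a Dirichlet radial basis,
#' vanishing on the bounding sphere). Coefficients are obtained by
#' weighted least squares over the voxel grid, which makes the composed
#' decompose/reconstruct operator an exact projection onto the truncated
#' basis: applying it twice equals applying it once.
#'
#' Truncation at low order (`L = N` of 5 or 7) yields a band-limited,
#' smoothed version of the label used for principal-axis extraction.
#'
#' @param x 3D numeric or logical array (a label indicator, or any
#'   non-negative intensity field).
#' @param voxel_size Scalar or length-3 voxel size, mm.
#' @param L Maximum spherical-harmonic degree, `>= 0`.
#' @param N Number of radial basis functions per degree, `>= 1`.
#' @param center Optional expansion centre (mm); default: the intensity
#'   centroid of `x`.
#' @param radius Optional domain radius (mm); default: the support's
#'   bounding-sphere radius about `center`, plus half a voxel diagonal.
#' @return Object of class `swd_coefficients`: coefficient vector with an
#'   `(l, m, n)` index table, truncation orders, domain radius, centre and
#'   the source grid geometry.
#' @export
swd_decompose <- function(x, voxel_size, L = 7L, N = 7L,
                          center = NULL, radius = NULL) {
  stopifnot(length(dim(x)) == 3L, L >= 0, N >= 1)
  xs <- as.numeric(x)
  dims <- dim(x)
  supp <- which(xs != 0)
  if (length(supp) == 0L)
    stop("volume is empty: nothing to decompose")
  idx_all <- arrayInd(seq_along(xs), dims)
  pts_all <- voxel_centers(idx_all, voxel_size)
  if (is.null(center)) {
    w <- abs(xs[supp])
    center <- colSums(pts_all[supp, , drop = FALSE] * w) / sum(w)
  }
  center <- as.numeric(center)
  rel_all <- sweep(pts_all, 2L, center)
  r_all <- sqrt(rowSums(rel_all^2))
  if (is.null(radius)) {
    vs <- rep_len(as.numeric(voxel_size), 3L)
    radius <- max(r_all[supp]) + sqrt(sum(vs^2)) / 2
  }
  stopifnot(radius > 0)
  in_dom <- which(r_all <= radius)
  A <- swd_basis_matrix(rel_all[in_dom, , drop = FALSE], radius, L, N)
  f <- xs[in_dom]
  G <- crossprod(A)
  coef <- drop(solve(G, crossprod(A, f)))
  structure(
    list(coefficients = coef, index = attr(A, "index"),
         L = as.integer(L), N = as.integer(N),
         domain_radius = radius, center = center,
         dim = dims, voxel_size = as.numeric(voxel_size)),
    class = "swd_coefficients")
}

#' @export
print.swd_coefficients <- function(x, ...) {
  cat(sprintf(
    "swd_coefficients: L = %d, N = %d (%d terms), domain radius %.2f mm\n",
    x$L, x$N, length(x$coefficients), x$domain_radius))
  invisible(x)
}

#' Reconstruct the smoothed volume from SWD coefficients
#'
#' Evaluates the truncated expansion on a voxel grid; the field is zero
#' outside the expansion's bounding sphere.
#'
#' @param coeff An `swd_coefficients` object from [swd_decompose()].
#' @param dim,voxel_size Target grid; defaults to the source grid stored
#'   in `coeff`. The grid must contain the expansion centre.
#' @return 3D numeric array: the band-limited smoothed field.
#' @export
swd_reconstruct <- function(coeff, dim = NULL, voxel_size = NULL) {
  stopifnot(inherits(coeff, "swd_coefficients"))
  if (is.null(dim)) dim <- coeff$dim
  if (is.null(voxel_size)) voxel_size <- coeff$voxel_size
  vs <- rep_len(as.numeric(voxel_size), 3L)
  if (any(coeff$center < 0) || any(coeff$center > dim * vs))
    stop("grid/domain mismatch: expansion centre lies outside the grid")
  out <- numeric(prod(dim))
  idx_all <- arrayInd(seq_along(out), dim)
  rel <- sweep(voxel_centers(idx_all, voxel_size), 2L, coeff$center)
  r <- sqrt(rowSums(rel^2))
  in_dom <- which(r <= coeff$domain_radius)
  if (length(in_dom)) {
    A <- swd_basis_matrix(rel[in_dom, , drop = FALSE],
                          coeff$domain_radius, coeff$L, coeff$N)
    out[in_dom] <- A %*% coeff$coefficients
  }
  array(out, dim)
}

#' Smooth a volume by truncated spherical-wave decomposition
#'
#' Convenience wrapper: [swd_decompose()] followed by
#' [swd_reconstruct()] on the same grid.
#'
#' @inheritParams swd_decompose
#' @return 3D numeric array of the smoothed field.
#' @export
swd_smooth <- function(x, voxel_size, L = 7L, N = 7L) {
  swd_reconstruct(swd_decompose(x, voxel_size, L = L, N = N))
}
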