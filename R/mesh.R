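#' Euler characteristic of a voxel solid
#'
#' Exact Euler characteristic of the cubical cell complex formed by the
#' union of the occupied voxels (vertices - edges + faces - cubes). A
#' voxelised ball gives 1, a solid torus 0 — the topological signature
#' distinguishing a blob from a doughnut.
#'
#' @param mask Logical 3D array of occupied voxels.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  p <- d + 2L
  occ <- array(FALSE, p)
  occ[2:(p[1] - 1), 2:(p[2] - 1), 2:(p[3] - 1)] <- as.logical(mask)
  sub <- function(o1, o2, o3) {
    occ[(1L + o1):(p[1] - 1L + o1),
        (1L + o2):(p[2] - 1L + o2),
        (1L + o3):(p[3] - 1L + o3), drop = FALSE]
  }
  C <- sum(mask)
  # vertices: lattice points touched by any of the 8 incident cubes
  V_arr <- sub(0L, 0L, 0L)
  for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                 c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)))
    V_arr <- V_arr | sub(o[1], o[2], o[3])
  V <- sum(V_arr)
  # edges along axis a: 4 incident cubes, offsets in the other two axes
  E <- 0
  offs2 <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (a in 1:3) {
    others <- setdiff(1:3, a)
    acc <- NULL
    for (o in offs2) {
      off <- c(0L, 0L, 0L)
      off[others] <- o
      # restrict the edge's own axis to interior cube slots
      idx <- lapply(1:3, function(ax) {
        if (ax == a) 2:(p[ax] - 1L)
        else (1L + off[ax]):(p[ax] - 1L + off[ax])
      })
      s <- occ[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      acc <- if (is.null(acc)) s else acc | s
    }
    E <- E + sum(acc)
  }
  # faces perpendicular to axis a: 2 incident cubes
  F <- 0
  for (a in 1:3) {
    acc <- NULL
    for (oa in 0:1) {
      idx <- lapply(1:3, function(ax) {
        if (ax == a) (1L + oa):(p[ax] - 1L + oa) else 2:(p[ax] - 1L)
      })
      s <- occ[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      acc <- if (is.null(acc)) s else acc | s
    }
    F <- F + sum(acc)
  }
  as.integer(V - E + F - C)
}

#' Boundary quad mesh of a voxel solid
#'
#' Extracts the closed surface of a voxelised solid as the set of unit
#' quads separating occupied from unoccupied voxels, with shared vertices
#' merged. For a handlebody solid the mesh's Euler characteristic
#' (`V - E + F`) is twice the solid's, so a solid torus yields a genus-1
#' surface with characteristic 0.
#'
#' @param mask Logical 3D array.
#' @param voxel_size Scalar voxel edge, mm.
#' @param origin mm coordinate of the grid corner (default 0,0,0).
#' @return List of class `quad_mesh`: `vertices` (n x 3, mm), `quads`
#'   (m x 4 vertex indices).
#' @export
boundary_quad_mesh <- function(mask, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  p <- d + 2L
  occ <- array(FALSE, p)
  occ[2:(p[1] - 1), 2:(p[2] - 1), 2:(p[3] - 1)] <- as.logical(mask)
  nlat <- d + 1L  # lattice points per axis
  vkey <- function(ijk)  # 1-based lattice index -> scalar key
    (ijk[, 1] - 1) + nlat[1] * ((ijk[, 2] - 1) + nlat[2] * (ijk[, 3] - 1))
  quads_keys <- list()
  for (a in 1:3) {
    lo_idx <- lapply(1:3, function(ax)
      if (ax == a) 1:(p[a] - 1L) else 2:(p[ax] - 1L))
    hi_idx <- lapply(1:3, function(ax)
      if (ax == a) 2:p[a] else 2:(p[ax] - 1L))
    lo <- occ[lo_idx[[1]], lo_idx[[2]], lo_idx[[3]], drop = FALSE]
    hi <- occ[hi_idx[[1]], hi_idx[[2]], hi_idx[[3]], drop = FALSE]
    face <- which(xor(lo, hi), arr.ind = TRUE)
    if (nrow(face) == 0L) next
    # the face's index along axis a is its lattice-plane coordinate; the
    # indices along the other two axes are the cube (= lower lattice
    # corner) coordinates, so the face matrix is the corner matrix
    others <- setdiff(1:3, a)
    corner <- unname(face)
    o1 <- o2 <- c(0L, 0L, 0L)
    o1[others[1]] <- 1L
    o2[others[2]] <- 1L
    k1 <- vkey(corner)
    k2 <- vkey(sweep(corner, 2L, o1, "+"))
    k3 <- vkey(sweep(corner, 2L, o1 + o2, "+"))
    k4 <- vkey(sweep(corner, 2L, o2, "+"))
    quads_keys[[a]] <- cbind(k1, k2, k3, k4)
  }
  qk <- do.call(rbind, quads_keys)
  if (is.null(qk) || nrow(qk) == 0L)
    stop("mask has no boundary (empty or full grid)")
  keys <- sort(unique(as.vector(qk)))
  quads <- matrix(match(as.vector(qk), keys), nrow(qk), 4L)
  ijk <- cbind(keys %% nlat[1],
               (keys %/% nlat[1]) %% nlat[2],
               keys %/% (nlat[1] * nlat[2]))  # 0-based lattice coords
  vertices <- sweep(ijk * voxel_size, 2L, as.numeric(origin), "+")
  structure(list(vertices = vertices, quads = quads), class = "quad_mesh")
}

#' Euler characteristic of a quad mesh, `V - E + F`
#' @param mesh A `quad_mesh` from [boundary_quad_mesh()].
#' @return Integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  stopifnot(inherits(mesh, "quad_mesh"))
  q <- mesh$quads
  ed <- rbind(q[, c(1, 2)], q[, c(2, 3)], q[, c(3, 4)], q[, c(4, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  nrow(mesh$vertices) - length(unique(key)) + nrow(q)
}

#' @export
print.quad_mesh <- function(x, ...) {
  cat(sprintf("quad_mesh: %d vertices, %d quads, Euler characteristic %d\n",
              nrow(x$vertices), nrow(x$quads),
              mesh_euler_characteristic(x)))
  invisible(x)
}

#' Voxelise a solid torus
#'
#' @param t A [torus()].
#' @param voxel_size Grid spacing, mm.
#' @return List: `mask`, `origin`, `voxel_size`.
#' @export
voxelize_torus <- function(t, voxel_size = 1) {
  stopifnot(inherits(t, "torus"), voxel_size > 0)
  ext <- t$R + t$b
  origin <- t$center - ext
  dims <- rep(as.integer(ceiling(2 * ext / voxel_size)), 3L)
  mask <- array(FALSE, dims)
  ij <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2])))
  xy <- sweep((ij - 0.5) * voxel_size, 2L, origin[1:2], "+")
  for (k in seq_len(dims[3])) {
    pts <- cbind(xy, origin[3] + (k - 0.5) * voxel_size)
    mask[, , k] <- torus_contains(pts, t)
  }
  list(mask = mask, origin = origin, voxel_size = voxel_size)
}

#' Surface mesh of a solid torus
#' @param t A [torus()].
#' @param voxel_size Voxelisation grid spacing, mm.
#' @return A `quad_mesh`.
#' @export
torus_mesh <- function(t, voxel_size = 1) {
  v <- voxelize_torus(t, voxel_size)
  boundary_quad_mesh(v$mask, v$voxel_size, v$origin)
}

#' Write a quad mesh to an ASCII PLY file
#'
#' @param mesh A `quad_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "quad_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$quads)),
               "property list uchar int vertex_indices", "end_header"),
             con)
  writeLines(apply(format(mesh$vertices, trim = TRUE), 1L, paste,
                   collapse = " "), con)
  writeLines(paste(4L, mesh$quads[, 1] - 1L, mesh$quads[, 2] - 1L,
                   mesh$quads[, 3] - 1L, mesh$quads[, 4] - 1L), con)
  invisible(path)
}
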