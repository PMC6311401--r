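#' Scalar voxel volume
#'
#' A regular scalar grid emulating a CBCT acquisition.  `origin` is the
#' lower corner of the grid; the center of voxel `[i, j, k]` (1-based) sits
#' at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param values 3D numeric array.
#' @param spacing per-axis voxel size in mm (scalar recycled to 3).
#' @param origin lower-corner coordinate (mm).
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3)
  spacing <- rep(as.double(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be > 0 on all axes")
  if (any(dim(values) < 1)) stop("grid must be non-empty")
  structure(list(values = values, spacing = spacing,
                 origin = as.double(origin)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              paste(dim(x$values), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Voxelize a watertight mesh into a binary occupancy volume
#'
#' Emulates CBCT discretization: a grid covering the mesh bounds plus a
#' 2-voxel margin, value 1 at voxel centers inside the mesh (ray-parity
#' test) and 0 outside.  Deterministic.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param spacing voxel size in mm (the CBCT emulation default is 0.3 mm).
#' @return a [voxel_volume()].
#' @export
voxelize <- function(mesh, spacing = 0.3) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (spacing <= 0) stop("spacing must be > 0")
  oe <- open_edge_count(mesh)
  if (oe > 0)
    stop("mesh is not watertight (", oe, " open edges); cannot voxelize")
  bb <- mesh_bbox(mesh)
  spacing3 <- rep(spacing, 3)
  dims <- pmax(1L, as.integer(ceiling((bb[2, ] - bb[1, ]) / spacing3))) + 4L
  origin <- bb[1, ] - 2 * spacing3
  inside <- .cpp_voxel_inside(mesh$vertices, mesh$faces, origin, spacing3,
                              dims)
  vals <- array(as.double(inside), dim = dims)
  if (sum(vals) == 0)
    warning("no voxel centers fall inside the mesh at spacing ", spacing,
            " mm; volume is empty")
  voxel_volume(vals, spacing3, origin)
}

# Separable Gaussian blur of a 3D array (sigma in voxels), zero padding.
gaussian_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(a)
  shift_axis <- function(x, k, axis) {
    out <- array(0, dim(x))
    n <- dim(x)[axis]
    if (abs(k) >= n) return(out)
    src <- if (k >= 0) 1:(n - k) else (1 - k):n
    dst <- if (k >= 0) (1 + k):n else 1:(n + k)
    idx_src <- list(1:d[1], 1:d[2], 1:d[3])
    idx_dst <- idx_src
    idx_src[[axis]] <- src
    idx_dst[[axis]] <- dst
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) {
    acc <- array(0, d)
    for (k in (-r):r) acc <- acc + w[k + r + 1] * shift_axis(a, k, axis)
    a <- acc
  }
  a
}

# 6-tetrahedron decomposition of the unit cube (corner ids 0..7, bit order
# x + 2y + 4z), all sharing the main diagonal 0-6.
TET_CORNERS <- matrix(c(0, 0, 0,
                        1, 0, 0,
                        1, 1, 0,
                        0, 1, 0,
                        0, 0, 1,
                        1, 0, 1,
                        1, 1, 1,
                        0, 1, 1), ncol = 3, byrow = TRUE)
TET_DECOMP <- matrix(c(1, 6, 2, 7,
                       1, 2, 3, 7,
                       1, 3, 4, 7,
                       1, 4, 8, 7,
                       1, 8, 5, 7,
                       1, 5, 6, 7), ncol = 4, byrow = TRUE)

#' Extract an isosurface mesh from a voxel volume
#'
#' Triangulates the iso-level surface by marching tetrahedra (each grid cube
#' split into six tetrahedra sharing the main diagonal; surface vertices by
#' linear interpolation along crossed edges).  Because a raw binary
#' occupancy grid has no sub-voxel information, a separable Gaussian
#' pre-filter (default `smooth_sigma = 0.8` voxel) is applied first: it
#' emulates the partial-volume grading of real CBCT intensities and removes
#' the corner-cutting surface-area bias of binary marching.  Set
#' `smooth_sigma = 0` to triangulate the raw grid.
#'
#' @param volume a [voxel_volume()].
#' @param threshold iso-level; must lie strictly between the grid's min and
#'   max values.
#' @param smooth_sigma Gaussian pre-filter width in voxels.
#' @return a [triangle_mesh()] with coordinates in mm.
#' @export
extract_isosurface <- function(volume, threshold, smooth_sigma = 0.8) {
  stopifnot(inherits(volume, "voxel_volume"))
  rng <- range(volume$values)
  if (!(threshold > rng[1] && threshold < rng[2]))
    stop("threshold ", threshold, " is not strictly inside the value range [",
         rng[1], ", ", rng[2], "]")
  pad <- max(2L, as.integer(ceiling(3 * smooth_sigma)))
  d0 <- dim(volume$values)
  d <- d0 + 2L * pad
  a <- array(rng[1], dim = d)
  a[pad + 1:d0[1], pad + 1:d0[2], pad + 1:d0[3]] <- volume$values
  a <- gaussian_blur3(a, smooth_sigma)

  nx <- d[1]; ny <- d[2]; nz <- d[3]
  cx <- nx - 1L; cy <- ny - 1L; cz <- nz - 1L
  # corner values for every cube, ncube x 8
  corner_slab <- function(dx, dy, dz)
    a[(1 + dx):(cx + dx), (1 + dy):(cy + dy), (1 + dz):(cz + dz)]
  CV <- matrix(NA_real_, cx * cy * cz, 8)
  for (ci in 1:8)
    CV[, ci] <- as.vector(corner_slab(TET_CORNERS[ci, 1], TET_CORNERS[ci, 2],
                                      TET_CORNERS[ci, 3]))
  act <- which(matrixStats_rowMax(CV) > threshold &
                 matrixStats_rowMin(CV) < threshold)
  if (length(act) == 0) stop("no surface crossings at this threshold")
  CV <- CV[act, , drop = FALSE]
  # cube lower-corner grid indices (0-based)
  i0 <- (act - 1) %% cx
  j0 <- ((act - 1) %/% cx) %% cy
  k0 <- (act - 1) %/% (cx * cy)
  base <- cbind(i0, j0, k0)

  tris <- vector("list", 64)
  nt <- 0
  thr <- threshold
  for (tet in seq_len(6)) {
    ids <- TET_DECOMP[tet, ]
    tv <- CV[, ids, drop = FALSE]
    tin <- tv > thr
    code <- tin[, 1] + 2L * tin[, 2] + 4L * tin[, 3] + 8L * tin[, 4]
    # corner grid offsets for this tetrahedron, 4 x 3
    off <- TET_CORNERS[ids, , drop = FALSE]
    interp <- function(rows, aa, bb) {
      va <- tv[rows, aa]; vb <- tv[rows, bb]
      t <- (thr - va) / (vb - va)
      pa <- base[rows, , drop = FALSE] +
        matrix(off[aa, ], length(rows), 3, byrow = TRUE)
      pb <- base[rows, , drop = FALSE] +
        matrix(off[bb, ], length(rows), 3, byrow = TRUE)
      pa + t * (pb - pa)
    }
    for (cd in 1:14) {
      rows <- which(code == cd)
      if (length(rows) == 0) next
      ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) != 0)
      outs <- setdiff(1:4, ins)
      if (length(ins) == 1 || length(ins) == 3) {
        aa <- if (length(ins) == 1) ins else outs
        oth <- setdiff(1:4, aa)
        q1 <- interp(rows, aa, oth[1])
        q2 <- interp(rows, aa, oth[2])
        q3 <- interp(rows, aa, oth[3])
        nt <- nt + 1; tris[[nt]] <- cbind(q1, q2, q3)
      } else {
        aa <- ins[1]; bb <- ins[2]; cc <- outs[1]; dd <- outs[2]
        q1 <- interp(rows, aa, cc)
        q2 <- interp(rows, aa, dd)
        q3 <- interp(rows, bb, dd)
        q4 <- interp(rows, bb, cc)
        nt <- nt + 1; tris[[nt]] <- cbind(q1, q2, q3)
        nt <- nt + 1; tris[[nt]] <- cbind(q1, q3, q4)
      }
    }
  }
  allt <- do.call(rbind, tris[seq_len(nt)])    # n x 9, grid units
  verts <- rbind(allt[, 1:3, drop = FALSE], allt[, 4:6, drop = FALSE],
                 allt[, 7:9, drop = FALSE])
  ntri <- nrow(allt)
  faces <- cbind(seq_len(ntri), seq_len(ntri) + ntri, seq_len(ntri) + 2 * ntri)
  # grid units -> mm: voxel center (0-based index i) is origin + (i + 0.5)*sp
  sp <- volume$spacing
  orig <- volume$origin - (pad - 0.5) * sp
  verts <- sweep(sweep(verts, 2, sp, `*`), 2, orig, `+`)
  mesh <- merge_mesh_vertices(verts, faces, tol = 1e-6)
  if (nrow(mesh$faces) == 0) stop("isosurface extraction produced no faces")
  mesh
}

# row min/max without extra deps
matrixStats_rowMax <- function(m) do.call(pmax, as.data.frame(m))
matrixStats_rowMin <- function(m) do.call(pmin, as.data.frame(m))
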