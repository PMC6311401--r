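#' Triangle mesh
#'
#' Construct a triangle surface mesh, the geometry carrier used throughout
#' the package for crowns, roots and isosurfaces.  Coordinates are in mm,
#' right-handed.
#'
#' @param vertices numeric matrix, n x 3, one vertex per row (mm).
#' @param faces integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param validate check invariants (indices in range, no repeated indices
#'   within a face, no zero-area faces above `1e-12` mm^2).
#' @return an object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- matrix(as.double(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3, dimnames = NULL)
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "triangle_mesh")
  if (validate) validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(v) == 0L || nrow(f) == 0L) stop("empty mesh")
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face index out of range (vertex count ", nrow(v), ")")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("face with repeated vertex indices")
  a <- face_areas(mesh)
  if (any(a <= 1e-12))
    stop("zero-area face (below 1e-12 mm^2 tolerance)")
  invisible(mesh)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

mesh_bbox <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2, min),
        hi = apply(mesh$vertices, 2, max))
}

# Merge vertices closer than `tol` (STL stores per-facet vertices) and drop
# faces that become degenerate.  Returns a triangle_mesh without validation
# so callers can inspect pathological inputs.
merge_mesh_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  newid <- match(key, key[first])
  v <- vertices[first, , drop = FALSE]
  f <- matrix(newid[faces], ncol = 3)
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  if (nrow(f) > 0) {
    m <- structure(list(vertices = v, faces = f), class = "triangle_mesh")
    keep2 <- face_areas(m) > 1e-12
    f <- f[keep2, , drop = FALSE]
  }
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

# Count mesh edges not shared by exactly two faces.
open_edge_count <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  sum(tab != 2L)
}

# Concatenate several meshes into one (vertex indices re-based).
merge_meshes <- function(meshes) {
  vs <- lapply(meshes, function(m) m$vertices)
  fs <- list()
  off <- 0L
  for (i in seq_along(meshes)) {
    fs[[i]] <- meshes[[i]]$faces + off
    off <- off + nrow(vs[[i]])
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs), validate = FALSE)
}

transform_mesh <- function(transform, mesh) {
  structure(list(vertices = apply_transform(transform, mesh$vertices),
                 faces = mesh$faces), class = "triangle_mesh")
}

#' Undirected 3D line
#'
#' A root long axis: a point plus a unit direction.  Lines are undirected
#' (`d` and `-d` describe the same line); [angle_between_lines()] respects
#' that convention.
#'
#' @param anchor 3D point on the line (mm).
#' @param direction 3D direction; normalized on construction.
#' @return object of class `line3d`.
#' @export
line3d <- function(anchor, direction) {
  anchor <- as.double(anchor)
  direction <- as.double(direction)
  stopifnot(length(anchor) == 3, length(direction) == 3)
  structure(list(anchor = anchor, direction = normalize(direction)),
            class = "line3d")
}

#' @export
print.line3d <- function(x, ...) {
  cat(sprintf("<line3d> anchor (%.3f, %.3f, %.3f)  direction (%.4f, %.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Plane in 3D
#'
#' @param point a point on the plane (mm).
#' @param normal plane normal; normalized on construction.
#' @return object of class `plane3d`.
#' @export
plane3d <- function(point, normal) {
  point <- as.double(point); normal <- as.double(normal)
  stopifnot(length(point) == 3, length(normal) == 3)
  structure(list(point = point, normal = normalize(normal)),
            class = "plane3d")
}

#' Closed planar outline
#'
#' An ordered closed polyline lying in one plane (a root cross-section
#' outline).  The first point is not repeated at the end; closure is
#' implicit.
#'
#' @param points n x 3 matrix of ordered points (n >= 3).
#' @param plane the [plane3d()] containing the outline.
#' @param tol maximum allowed out-of-plane distance (mm).
#' @return object of class `outline_loop`.
#' @export
outline_loop <- function(points, plane, tol = 1e-6) {
  points <- matrix(as.double(points), ncol = 3)
  if (nrow(points) < 3) stop("an outline loop needs at least 3 points")
  d <- (points - matrix(plane$point, nrow(points), 3, byrow = TRUE)) %*%
    plane$normal
  if (max(abs(d)) > tol)
    stop("outline points are not within ", tol, " mm of the plane")
  structure(list(points = points, plane = plane), class = "outline_loop")
}

loop_perimeter <- function(loop) {
  p <- loop$points
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((q - p)^2)))
}

loop_area <- function(loop) {
  b <- perp_basis(loop$plane$normal)
  p <- loop$points
  rel <- p - matrix(loop$plane$point, nrow(p), 3, byrow = TRUE)
  x <- rel %*% b$u; y <- rel %*% b$v
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

loop_centroid <- function(loop) colMeans(loop$points)

#' Orthogonal best-fit line through a 3D point cloud
#'
#' Total-least-squares line: anchored at the centroid, directed along the
#' first principal direction of the centered points (the direction
#' minimizing total squared orthogonal distance).  The returned direction is
#' sign-canonicalized (lexicographically larger of the two equivalent
#' directions) so results are deterministic.
#'
#' @param points n x 3 matrix, n >= 2, not all coincident.
#' @return a [line3d()].
#' @details If the two leading singular values are equal within `1e-9` the
#'   direction is not unique; a warning is emitted and the deterministic
#'   sign rule picks one representative.
#' @export
best_fit_line <- function(points) {
  points <- matrix(as.double(points), ncol = 3)
  if (nrow(points) < 2) stop("need at least 2 points to fit a line")
  if (nrow(unique(points)) < 2) stop("need at least 2 distinct points")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  s <- svd(x, nu = 0, nv = 3)
  if (s$d[1] - s$d[2] < 1e-9)
    warning("degenerate (isotropic) point set: line direction is not unique; ",
            "deterministic tie-break applied")
  line3d(ctr, canonical_direction(s$v[, 1]))
}

#' Angle between two undirected lines
#'
#' `acos(|d1 . d2|)` in degrees, in `[0, 90]`; symmetric and invariant to
#' flipping either direction.  This is the axes angle (AA) metric when
#' applied to a predicted and a CBCT-derived root axis.
#'
#' @param a,b [line3d()] objects.
#' @return angle in degrees.
#' @export
angle_between_lines <- function(a, b) {
  stopifnot(inherits(a, "line3d"), inherits(b, "line3d"))
  d <- abs(sum(a$direction * b$direction))
  acos(min(1, d)) * 180 / pi
}
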