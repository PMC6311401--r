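#' Area-uniform random points on a mesh surface
#'
#' Draws `n` points uniformly by area: a face is chosen with probability
#' proportional to its area and the point is placed barycentric-uniformly
#' within it.  Used to emulate the "points placed uniformly on the root
#' surface" step of the predicted-root axis estimator.  Fully deterministic
#' given `seed`.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of points, `n >= 1`.
#' @param seed integer RNG seed.
#' @param exclude optional predicate: a function taking the m x 3 matrix of
#'   face centroids and returning a logical vector, `TRUE` for faces to
#'   exclude from sampling (e.g. an apical cap).
#' @return n x 3 matrix of surface points.
#' @export
surface_sample_uniform <- function(mesh, n, seed = 1L, exclude = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1")
  areas <- face_areas(mesh)
  keep <- rep(TRUE, length(areas))
  if (!is.null(exclude)) keep <- !exclude(face_centroids(mesh))
  if (!any(keep) || sum(areas[keep]) <= 0)
    stop("exclusion predicate removed all mesh faces")
  idx_keep <- which(keep)
  with_seed(seed, {
    fi <- idx_keep[sample.int(length(idx_keep), n, replace = TRUE,
                              prob = areas[idx_keep])]
    barycentric_points(mesh, fi, n)
  })
}

barycentric_points <- function(mesh, fi, n) {
  r1 <- runif(n); r2 <- runif(n)
  flip <- r1 + r2 > 1
  r1[flip] <- 1 - r1[flip]
  r2[flip] <- 1 - r2[flip]
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[fi, 1], , drop = FALSE]
  b <- v[f[fi, 2], , drop = FALSE]
  c_ <- v[f[fi, 3], , drop = FALSE]
  a + r1 * (b - a) + r2 * (c_ - a)
}

#' Stratified area-uniform points on a mesh surface
#'
#' Like [surface_sample_uniform()] but with the cumulative face-area
#' measure divided into `n` equal strata and one point drawn per stratum
#' (uniform within it).  Marginally each point is still exactly
#' area-uniform, but the set is spread evenly over the surface, which cuts
#' the orientation noise of a line fit by an order of magnitude at small
#' `n` -- the behaviour expected of points "placed uniformly" on a root by
#' an operator or by software.
#'
#' @inheritParams surface_sample_uniform
#' @return n x 3 matrix of surface points.
#' @export
surface_sample_stratified <- function(mesh, n, seed = 1L, exclude = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1")
  areas <- face_areas(mesh)
  keep <- rep(TRUE, length(areas))
  if (!is.null(exclude)) keep <- !exclude(face_centroids(mesh))
  if (!any(keep) || sum(areas[keep]) <= 0)
    stop("exclusion predicate removed all mesh faces")
  idx_keep <- which(keep)
  cum <- cumsum(areas[idx_keep])
  total <- cum[length(cum)]
  with_seed(seed, {
    u <- (seq_len(n) - runif(n)) * total / n
    fi <- idx_keep[findInterval(u, cum) + 1L]
    barycentric_points(mesh, fi, n)
  })
}
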