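#' Rigid transform
#'
#' Rotation plus translation mapping the digital-model (scanner) frame into
#' the CBCT frame: `y = R x + t`.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.double(rotation), 3, 3)
  translation <- as.double(translation)
  stopifnot(length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal within 1e-9")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must have determinant +1 (no reflections)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rotation angle %.3f deg, translation %.3f mm\n",
              rotation_angle_deg(x), vnorm(x$translation)))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix or length-3 vector.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  single <- is.null(dim(points))
  p <- matrix(as.double(points), ncol = 3)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (single) as.vector(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform applying `b` first, then
#' `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.vector(t(transform$rotation) %*% transform$translation))
}

#' Rotation angle of a rigid transform
#' @param transform a [rigid_transform()].
#' @return the rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(transform) {
  R <- transform$rotation
  # atan2 form is accurate for small angles where acos((tr-1)/2) loses
  # precision
  s <- 0.5 * sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
                    (R[2, 1] - R[1, 2])^2)
  c_ <- (sum(diag(R)) - 1) / 2
  atan2(s, c_) * 180 / pi
}

#' Map a line through a rigid transform
#' @param transform a [rigid_transform()].
#' @param line a [line3d()].
#' @return the transformed [line3d()].
#' @export
transform_line <- function(transform, line) {
  line3d(apply_transform(transform, line$anchor),
         as.vector(transform$rotation %*% line$direction))
}

# Random rigid transform: rotation about a uniformly random axis by an angle
# uniform in [0, rot_deg_max], translation in a uniformly random direction
# with magnitude uniform in [0, trans_mm_max].  Uses the ambient RNG stream.
random_rigid_transform <- function(rot_deg_max, trans_mm_max) {
  ax <- normalize(rnorm(3))
  ang <- runif(1, 0, rot_deg_max)
  dir <- normalize(rnorm(3))
  mag <- runif(1, 0, trans_mm_max)
  rigid_transform(rotation_about_axis(ax, ang), dir * mag)
}

#' Least-squares rigid alignment of corresponding landmarks
#'
#' Kabsch algorithm: the rigid transform minimizing
#' \eqn{\sum_i \|T(s_i) - t_i\|^2} over corresponded point pairs, via SVD of
#' the cross-covariance of the centered sets, with reflection correction.
#' This emulates the initial manual alignment of a digital model to the
#' CBCT surface from matched anatomical landmarks.
#'
#' @param source_points n x 3 matrix, n >= 3, non-collinear.
#' @param target_points n x 3 matrix of corresponding points.
#' @return a [rigid_transform()].
#' @export
landmark_align <- function(source_points, target_points) {
  s <- matrix(as.double(source_points), ncol = 3)
  t_ <- matrix(as.double(target_points), ncol = 3)
  if (nrow(s) != nrow(t_))
    stop("source and target landmark counts differ (", nrow(s), " vs ",
         nrow(t_), ")")
  if (nrow(s) < 3) stop("need at least 3 landmark pairs")
  cs <- colMeans(s); ct <- colMeans(t_)
  sc <- sweep(s, 2, cs); tc <- sweep(t_, 2, ct)
  ev <- eigen(crossprod(sc), symmetric = TRUE, only.values = TRUE)$values
  if (sqrt(max(0, ev[2])) < 1e-6 * max(1, sqrt(ev[1])))
    stop("landmarks are collinear or coincident; rigid alignment is degenerate")
  H <- crossprod(sc, tc)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  rigid_transform(R, ct - as.vector(R %*% cs))
}

#' ICP configuration
#'
#' @param max_iterations maximum ICP iterations.
#' @param rms_tolerance stop when the kept-pair RMS changes by less than
#'   this (mm).
#' @param trim_fraction fraction of closest correspondences kept each
#'   iteration (trimmed ICP); `1` gives classical ICP.
#' @param source_sample_count surface points sampled from the source mesh
#'   (fixed across iterations).
#' @param seed RNG seed for the source sampling.
#' @return object of class `icp_config`.
#' @export
icp_config <- function(max_iterations = 50L, rms_tolerance = 1e-6,
                       trim_fraction = 0.9, source_sample_count = 5000L,
                       seed = 1L) {
  stopifnot(max_iterations >= 1, trim_fraction > 0, trim_fraction <= 1,
            rms_tolerance >= 0, source_sample_count >= 3)
  structure(list(max_iterations = as.integer(max_iterations),
                 rms_tolerance = rms_tolerance,
                 trim_fraction = trim_fraction,
                 source_sample_count = as.integer(source_sample_count),
                 seed = as.integer(seed)),
            class = "icp_config")
}

#' Trimmed iterative-closest-point refinement
#'
#' Refines an initial rigid alignment of `source` onto `target` by
#' alternating (i) true closest points on the target surface
#' (point-to-triangle, grid-accelerated) for a fixed seeded sample of source
#' surface points, (ii) trimming to the closest `trim_fraction` of pairs,
#' and (iii) a Kabsch update.  Iteration stops when the kept-pair RMS
#' changes by less than `rms_tolerance` or after `max_iterations`.
#'
#' @param source,target [triangle_mesh()] objects (crown surfaces in the
#'   registration workflow).
#' @param init initial [rigid_transform()] (e.g. from [landmark_align()]).
#' @param config an [icp_config()].
#' @return list with `transform` (composed with `init`), `final_rms` (mm,
#'   over kept pairs), `iterations`, and `rms_history`.
#' @export
icp_refine <- function(source, target, init = rigid_transform(),
                       config = icp_config()) {
  stopifnot(inherits(source, "triangle_mesh"),
            inherits(target, "triangle_mesh"),
            inherits(init, "rigid_transform"))
  src_pts <- surface_sample_uniform(source, config$source_sample_count,
                                    seed = config$seed)
  # sanity check: do the frames overlap at all after initialization?
  sb <- apply(apply_transform(init, src_pts), 2, range)
  tb <- mesh_bbox(target)
  margin <- 0.25 * max(tb[2, ] - tb[1, ]) + 1
  if (any(sb[1, ] > tb[2, ] + margin) || any(sb[2, ] < tb[1, ] - margin))
    stop("source and target do not overlap after initialization; ",
         "provide a better initial alignment")

  T_cur <- init
  n_keep <- max(3L, as.integer(ceiling(config$trim_fraction *
                                         nrow(src_pts))))
  index <- .cpp_mesh_index(target$vertices, target$faces)
  prev_rms <- Inf
  rms_history <- numeric(0)
  iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    p <- apply_transform(T_cur, src_pts)
    cp <- .cpp_closest_points_indexed(index, p)
    keep <- order(cp$dist)[seq_len(n_keep)]
    rms <- sqrt(mean(cp$dist[keep]^2))
    rms_history <- c(rms_history, rms)
    delta <- landmark_align(p[keep, , drop = FALSE],
                            cp$points[keep, , drop = FALSE])
    T_cur <- compose_transforms(delta, T_cur)
    if (abs(prev_rms - rms) < config$rms_tolerance) break
    prev_rms <- rms
  }
  list(transform = T_cur, final_rms = rms_history[length(rms_history)],
       iterations = iter, rms_history = rms_history)
}
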