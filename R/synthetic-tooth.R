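# Parametric anterior-tooth phantoms with known ground-truth root axes.

ANTERIOR_FDI <- c(11L, 12L, 13L, 21L, 22L, 23L, 31L, 32L, 33L, 41L, 42L, 43L)

#' Shape parameters for a synthetic anterior tooth
#'
#' The root is a tapered elliptical tube from cervix to apex; the crown a
#' closed cap above the cervical margin.  Dimensions are in mm.
#'
#' @param root_length cervix-to-apex length (8-30 mm for permanent anterior
#'   teeth).
#' @param cervical_radius_mesiodistal,cervical_radius_labiolingual semi-axes
#'   of the elliptical cervical cross-section.
#' @param taper_exponent radius scales as `(1 - t)^taper_exponent` along the
#'   root; in `(0.5, 3]`.
#' @param apical_curve_deg gradual apical deviation, applied progressively
#'   over the apical third; in `[0, 30]` degrees.
#' @param crown_height cervix-to-incisal-edge height.
#' @param mesh_resolution segments per cross-section ring.
#' @return object of class `tooth_shape_params`.
#' @export
tooth_shape_params <- function(root_length = 13,
                               cervical_radius_mesiodistal = 3.0,
                               cervical_radius_labiolingual = 3.2,
                               taper_exponent = 1.0,
                               apical_curve_deg = 5,
                               crown_height = 10,
                               mesh_resolution = 24L) {
  stopifnot(root_length > 0, cervical_radius_mesiodistal > 0,
            cervical_radius_labiolingual > 0, crown_height > 0,
            taper_exponent > 0.5, taper_exponent <= 3,
            apical_curve_deg >= 0, apical_curve_deg <= 30,
            mesh_resolution >= 8)
  structure(list(root_length = root_length,
                 cervical_radius_mesiodistal = cervical_radius_mesiodistal,
                 cervical_radius_labiolingual = cervical_radius_labiolingual,
                 taper_exponent = taper_exponent,
                 apical_curve_deg = apical_curve_deg,
                 crown_height = crown_height,
                 mesh_resolution = as.integer(mesh_resolution)),
            class = "tooth_shape_params")
}

#' Default shape parameters per tooth class
#'
#' Averages by tooth position: central incisors, lateral incisors and
#' canines; canines get longer roots and more apical curvature, mirroring
#' their anatomy (and the clinical finding that canine root prediction is
#' hardest).
#'
#' @param label FDI code of a permanent anterior tooth (11-13, 21-23,
#'   31-33, 41-43).
#' @return a [tooth_shape_params()].
#' @export
default_shape_params <- function(label) {
  label <- check_fdi(label)
  pos <- label %% 10L            # 1 central, 2 lateral, 3 canine
  upper <- label %/% 10L <= 2L
  if (pos == 1L) {
    if (upper) tooth_shape_params(13.0, 3.2, 3.1, 1.0, 3, 10.5)
    else       tooth_shape_params(12.5, 1.8, 2.9, 1.0, 3, 8.8)
  } else if (pos == 2L) {
    if (upper) tooth_shape_params(13.0, 2.4, 2.9, 1.0, 5, 9.0)
    else       tooth_shape_params(13.5, 2.0, 3.0, 1.0, 5, 9.3)
  } else {
    if (upper) tooth_shape_params(16.5, 2.8, 3.8, 1.1, 10, 10.0)
    else       tooth_shape_params(15.5, 2.6, 3.6, 1.1, 10, 10.5)
  }
}

check_fdi <- function(label) {
  label <- as.integer(label)
  if (!(label %in% ANTERIOR_FDI))
    stop("label must be a permanent anterior FDI code (",
         paste(ANTERIOR_FDI, collapse = ", "), "); got ", label)
  label
}

# Centerline stations of the root.  t runs 0 (cervix) to 1 (apex); the
# direction starts along -z and, over the apical third, tilts progressively
# in the y-z plane up to apical_curve_deg at the apex.
root_centerline <- function(params, t) {
  L <- params$root_length
  nt <- length(t)
  fine <- seq(0, 1, length.out = 201)
  th <- ifelse(fine <= 2 / 3, 0,
               params$apical_curve_deg * (3 * (fine - 2 / 3))) * pi / 180
  dirs <- cbind(0, sin(th), -cos(th))
  step <- L / (length(fine) - 1)
  pos <- rbind(c(0, 0, 0),
               apply(dirs[-nrow(dirs), , drop = FALSE] * step, 2, cumsum))
  centers <- matrix(NA_real_, nt, 3)
  dirout <- matrix(NA_real_, nt, 3)
  for (i in seq_len(nt)) {
    j <- 1 + (length(fine) - 1) * t[i]
    j0 <- floor(j); fr <- j - j0
    j1 <- min(j0 + 1, length(fine))
    centers[i, ] <- pos[j0, ] * (1 - fr) + pos[j1, ] * fr
    dirout[i, ] <- normalize(dirs[j0, ] * (1 - fr) + dirs[j1, ] * fr)
  }
  list(centers = centers, directions = dirout)
}

ring_vertices <- function(center, dir, a, b, resolution) {
  u <- c(1, 0, 0)                       # bending stays in the y-z plane
  v <- normalize(cross3(dir, u))
  phi <- 2 * pi * (seq_len(resolution) - 1) / resolution
  outer(rep(1, resolution), center) +
    outer(a * cos(phi), u) + outer(b * sin(phi), v)
}

# Stitch consecutive rings (each res vertices, stacked in `verts`) plus end
# caps into a watertight tube.  `top_center`/`bottom_center` are apex/fan
# points appended to the vertex list.
tube_mesh <- function(rings, top_point, bottom_point) {
  res <- nrow(rings[[1]])
  nr <- length(rings)
  verts <- do.call(rbind, rings)
  vtop <- nrow(verts) + 1L
  vbot <- nrow(verts) + 2L
  verts <- rbind(verts, top_point, bottom_point)
  idx <- function(r, k) (r - 1L) * res + ((k - 1L) %% res) + 1L
  faces <- vector("list", nr + 1)
  k <- seq_len(res)
  faces[[1]] <- cbind(rep(vtop, res), idx(1, k), idx(1, k + 1))
  for (r in seq_len(nr - 1)) {
    f1 <- cbind(idx(r, k), idx(r + 1, k), idx(r + 1, k + 1))
    f2 <- cbind(idx(r, k), idx(r + 1, k + 1), idx(r, k + 1))
    faces[[r + 1]] <- rbind(f1, f2)
  }
  faces[[nr + 1]] <- cbind(rep(vbot, res), idx(nr, k + 1), idx(nr, k))
  triangle_mesh(verts, do.call(rbind, faces))
}

#' Generate a synthetic anterior tooth
#'
#' Builds a watertight crown + root phantom with a known ground-truth root
#' axis.  The root is a tapered (optionally apically curved) elliptical
#' tube; the ground-truth axis is the best-fit line through the ring
#' centers of the cervical 80% of the root, matching the region measured by
#' the CBCT-side estimator.  Mild seeded per-ring radius variation adds
#' shape individuality without moving the centerline.
#'
#' @param label FDI code (permanent anterior).
#' @param params a [tooth_shape_params()]; defaults per tooth class.
#' @param seed integer seed for shape variation.
#' @return object of class `tooth_model` with elements `label`, `crown`,
#'   `root` ([triangle_mesh()]s), `cervix_center`, `apex`, `true_axis`
#'   (a [line3d()]).
#' @export
generate_tooth <- function(label, params = default_shape_params(label),
                           seed = 1L) {
  label <- check_fdi(label)
  stopifnot(inherits(params, "tooth_shape_params"))
  res <- params$mesh_resolution
  L <- params$root_length
  n_rings <- max(14L, as.integer(ceiling(L / 0.7)))
  tt <- (seq_len(n_rings) - 1) / n_rings      # last ring short of the apex
  cl <- root_centerline(params, c(tt, 1))
  centers <- cl$centers[seq_len(n_rings), , drop = FALSE]
  dirs <- cl$directions[seq_len(n_rings), , drop = FALSE]
  apex <- cl$centers[n_rings + 1, ]

  taper <- (1 - tt)^params$taper_exponent
  wob <- with_seed(seed, 1 + 0.02 * rnorm(n_rings))
  a <- params$cervical_radius_mesiodistal * taper * wob
  b <- params$cervical_radius_labiolingual * taper * wob

  rings <- lapply(seq_len(n_rings), function(i)
    ring_vertices(centers[i, ], dirs[i, ], a[i], b[i], res))
  root <- tube_mesh(rings, top_point = c(0, 0, 0), bottom_point = apex)

  keep <- tt <= 0.8
  true_axis <- if (params$apical_curve_deg == 0) {
    line3d(c(0, 0, 0), c(0, 0, 1))
  } else {
    best_fit_line(centers[keep, , drop = FALSE])
  }

  # crown: rings from the exact cervical ring up to the incisal edge
  n_c <- 9L
  psi <- seq(0, pi / 2, length.out = n_c + 1)[seq_len(n_c)]
  scale <- cos(psi)^0.45
  z <- params$crown_height * sin(psi)
  crown_rings <- lapply(seq_len(n_c), function(i) {
    ring_vertices(c(0, 0, z[i]), c(0, 0, -1),
                  a[1] * scale[i], b[1] * scale[i], res)
  })
  # order rings from incisal tip down to the cervix so the tube's "top" cap
  # is the incisal point and the "bottom" cap is the cervical disk
  crown <- tube_mesh(rev(crown_rings),
                     top_point = c(0, 0, params$crown_height),
                     bottom_point = c(0, 0, 0))

  model <- structure(list(label = label, crown = crown, root = root,
                          cervix_center = c(0, 0, 0), apex = apex,
                          true_axis = true_axis, params = params),
                     class = "tooth_model")
  rl <- vnorm(model$apex - model$cervix_center)
  if (rl < 8 || rl > 30)
    stop("root length ", signif(rl, 4), " mm outside the 8-30 mm range")
  model
}

#' @export
print.tooth_model <- function(x, ...) {
  cat(sprintf("<tooth_model> FDI %d: crown %d faces, root %d faces, root length %.1f mm\n",
              x$label, nrow(x$crown$faces), nrow(x$root$faces),
              vnorm(x$apex - x$cervix_center)))
  invisible(x)
}

transform_tooth <- function(transform, tooth) {
  tooth$crown <- transform_mesh(transform, tooth$crown)
  tooth$root <- transform_mesh(transform, tooth$root)
  tooth$cervix_center <- apply_transform(transform, tooth$cervix_center)
  tooth$apex <- apply_transform(transform, tooth$apex)
  if (!is.null(tooth$true_axis))
    tooth$true_axis <- transform_line(transform, tooth$true_axis)
  tooth
}

#' Inject a known angular error into a tooth's root
#'
#' Stand-in for the proprietary virtual-root construction: returns a copy
#' of the tooth whose root mesh is rotated by `error_deg` about an axis
#' through the cervix center perpendicular to the true axis (at the given
#' azimuth), optionally with small seeded vertex jitter.  The crown is
#' unchanged, so crown-based registration is unaffected by the injected
#' root error.
#'
#' @param tooth a [generate_tooth()] model carrying a `true_axis`.
#' @param error_deg injected angular error, `0 <= error_deg <= 45`.
#' @param azimuth_deg direction of the tilt within the plane perpendicular
#'   to the true axis.
#' @param seed seed for the vertex jitter.
#' @param jitter_sd standard deviation of per-vertex Gaussian jitter (mm);
#'   `0` disables.
#' @return a `tooth_model` whose root (and `true_axis`/`apex`) are rotated.
#' @export
perturb_predicted_root <- function(tooth, error_deg, azimuth_deg = 0,
                                   seed = 1L, jitter_sd = 0.05) {
  stopifnot(inherits(tooth, "tooth_model"), !is.null(tooth$true_axis))
  if (error_deg < 0 || error_deg > 45)
    stop("error_deg must be in [0, 45]")
  w <- tooth$true_axis$direction
  bs <- perp_basis(w)
  az <- azimuth_deg * pi / 180
  axis <- cos(az) * bs$u + sin(az) * bs$v
  R <- rotation_about_axis(axis, error_deg)
  piv <- tooth$cervix_center
  rot_about_pivot <- rigid_transform(R, piv - as.vector(R %*% piv))

  out <- tooth
  out$root <- transform_mesh(rot_about_pivot, tooth$root)
  out$apex <- apply_transform(rot_about_pivot, tooth$apex)
  out$true_axis <- transform_line(rot_about_pivot, tooth$true_axis)
  if (jitter_sd > 0) {
    out$root$vertices <- out$root$vertices +
      with_seed(seed, matrix(rnorm(length(out$root$vertices), 0, jitter_sd),
                             ncol = 3))
  }
  out
}
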