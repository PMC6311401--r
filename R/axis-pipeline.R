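#' Slice/sampling plan for the root-axis estimators
#'
#' Configuration of the two root-axis estimators: the CBCT-side estimator
#' slices the root perpendicular to its preliminary axis at fractions of
#' the cervix-to-apex distance (default 0%, 20%, 40%, 60%, 80%) and places
#' 4 or 5 equidistant landmarks on each outline; the predicted-root
#' estimator fits 50 area-uniform surface points with the apical cap
#' excluded.
#'
#' @param positions strictly increasing fractions in `[0, 0.95]`.
#' @param landmarks_per_outline 4 or 5.
#' @param apex_exclusion_fraction fraction of root length near the apex
#'   excluded from surface sampling (the apex is too variable to use).
#' @param surface_sample_count points for the predicted-root estimator.
#' @param seed RNG seed for the surface sampling.
#' @return object of class `slice_plan`.
#' @export
slice_plan <- function(positions = c(0, 0.2, 0.4, 0.6, 0.8),
                       landmarks_per_outline = 4L,
                       apex_exclusion_fraction = 0.10,
                       surface_sample_count = 50L,
                       seed = 1L) {
  positions <- as.double(positions)
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(positions < 0 | positions > 0.95))
    stop("positions must lie within [0, 0.95]")
  if (!(landmarks_per_outline %in% c(4L, 5L)))
    stop("landmarks_per_outline must be 4 or 5")
  stopifnot(apex_exclusion_fraction >= 0, apex_exclusion_fraction < 1,
            surface_sample_count >= 2)
  structure(list(positions = positions,
                 landmarks_per_outline = as.integer(landmarks_per_outline),
                 apex_exclusion_fraction = apex_exclusion_fraction,
                 surface_sample_count = as.integer(surface_sample_count),
                 seed = as.integer(seed)),
            class = "slice_plan")
}

#' Preliminary (bootstrap) root axis
#'
#' Principal direction of the root vertex cloud, oriented from the cervix
#' side to the apex side (the cervix end has the larger cross-section, so
#' it shows the larger mean radial spread about the axis).  The slice
#' positions and the apical exclusion of the two estimators are measured
#' along this axis.
#'
#' @param root a root [triangle_mesh()].
#' @return a [line3d()] oriented cervix -> apex.
#' @export
preliminary_axis <- function(root) {
  stopifnot(inherits(root, "triangle_mesh"))
  v <- root$vertices
  ctr <- colMeans(v)
  x <- sweep(v, 2, ctr)
  sv <- svd(x, nu = 0, nv = 3)
  if (sv$d[1] < 1.5 * sv$d[2])
    stop("root mesh is isotropic; no well-defined long axis")
  dir <- canonical_direction(sv$v[, 1])
  s <- as.vector(x %*% dir)
  r <- sqrt(pmax(0, rowSums(x^2) - s^2))
  lower <- s <= median(s)
  if (mean(r[!lower]) > mean(r[lower])) dir <- -dir
  line3d(ctr, dir)
}

#' Root axis from uniformly placed surface points (digital-model side)
#'
#' The predicted-root axis estimator: `surface_sample_count` points placed
#' uniformly over the root surface -- excluding the apical
#' `apex_exclusion_fraction` of the root length, measured along the
#' preliminary axis (the apex is too variable to use) -- then a
#' total-least-squares line fit.
#'
#' The default placement (`method = "rings"`) spreads the points the way
#' software or an operator places them: levels equally spaced along the
#' preliminary axis, five points per level equally spaced along the
#' surface outline, with a seeded random azimuthal phase per level.
#' Balanced placement is essential: randomly drawn surface points carry
#' several degrees of line-fit orientation noise at 50 points, an order of
#' magnitude above the known repeatability of the measurement.
#' `method = "stratified"` (area-stratified random draws) and
#' `method = "iid"` (independent area-uniform draws) are available for
#' noise studies.
#'
#' @param root a root [triangle_mesh()].
#' @param spec a [slice_plan()].
#' @param method point placement: `"rings"` (default), `"stratified"`, or
#'   `"iid"`.
#' @return a [line3d()].
#' @export
predicted_root_axis <- function(root, spec = slice_plan(),
                                method = c("rings", "stratified", "iid")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "slice_plan"))
  pre <- preliminary_axis(root)
  sv <- as.vector(sweep(root$vertices, 2, pre$anchor) %*% pre$direction)
  smax <- max(sv); smin <- min(sv)
  cutoff <- smax - spec$apex_exclusion_fraction * (smax - smin)
  if (spec$surface_sample_count < 10)
    warning("surface_sample_count = ", spec$surface_sample_count,
            " is very low; the fitted axis will be noisy")
  if (method == "rings") {
    per_level <- 5L
    n_levels <- max(2L, as.integer(round(spec$surface_sample_count /
                                           per_level)))
    span <- cutoff - smin
    levels <- smin + span * (seq_len(n_levels) - 0.5) / n_levels
    phases <- with_seed(spec$seed, runif(n_levels))
    pts <- list()
    for (li in seq_along(levels)) {
      q <- pre$anchor + levels[li] * pre$direction
      loops <- plane_mesh_intersection(root, plane3d(q, pre$direction))
      if (length(loops) == 0) next
      dists <- vapply(loops, function(lp) {
        rel <- loop_centroid(lp) - pre$anchor
        vnorm(rel - sum(rel * pre$direction) * pre$direction)
      }, numeric(1))
      lp <- loops[[which.min(dists)]]
      fr <- (seq_len(per_level) - 1) / per_level + phases[li]
      pts[[length(pts) + 1]] <- loop_points_at_fractions(lp, fr)
    }
    if (length(pts) < 2)
      stop("could not place surface points on the root (too few usable levels)")
    return(best_fit_line(do.call(rbind, pts)))
  }
  excl <- function(centroids) {
    as.vector(sweep(centroids, 2, pre$anchor) %*% pre$direction) > cutoff
  }
  sampler <- if (method == "stratified") surface_sample_stratified
             else surface_sample_uniform
  pts <- sampler(root, spec$surface_sample_count, seed = spec$seed,
                 exclude = excl)
  best_fit_line(pts)
}

#' Root axis from cross-section outline landmarks (CBCT side)
#'
#' The CBCT-side axis estimator: the root is sliced perpendicular to its
#' preliminary axis at the plan's fractional positions of the
#' cervix-to-apex distance; at each position the outline nearest the axis
#' is kept and `landmarks_per_outline` equidistant landmarks are placed on
#' it; the axis is the total-least-squares line through all landmarks
#' (typically 20-25 points).
#'
#' @param root a root [triangle_mesh()] (synthetic or isosurface-derived).
#' @param spec a [slice_plan()].
#' @return a [line3d()] with attribute `n_slices` (usable slice count).
#' @export
cbct_root_axis <- function(root, spec = slice_plan()) {
  stopifnot(inherits(spec, "slice_plan"))
  pre <- preliminary_axis(root)
  sv <- as.vector(sweep(root$vertices, 2, pre$anchor) %*% pre$direction)
  s0 <- min(sv); s1 <- max(sv)
  L <- s1 - s0
  # keep boundary slices inside the mesh: a plane through the extreme vertex
  # cuts an end cap obliquely whenever the preliminary axis is slightly
  # tilted, yielding a partial rim outline far off-axis
  eps <- 0.02 * L
  landmarks <- list()
  areas_used <- numeric(0)
  for (f in spec$positions) {
    s_f <- min(max(s0 + f * L, s0 + eps), s1 - eps)
    q <- pre$anchor + s_f * pre$direction
    pl <- plane3d(q, pre$direction)
    loops <- plane_mesh_intersection(root, pl)
    if (length(loops) > 0) {
      dists <- vapply(loops, function(lp) {
        rel <- loop_centroid(lp) - pre$anchor
        vnorm(rel - sum(rel * pre$direction) * pre$direction)
      }, numeric(1))
      r_eff <- vapply(loops, function(lp) sqrt(loop_area(lp) / pi),
                      numeric(1))
      ok <- dists < pmax(0.75 * r_eff, 0.3)
      loops <- loops[ok]
      dists <- dists[ok]
    }
    if (length(loops) == 0) {
      warning("no usable outline at slice position ", f, "; slice skipped")
      next
    }
    lp <- loops[[which.min(dists)]]
    landmarks[[length(landmarks) + 1]] <-
      equidistant_landmarks(lp, spec$landmarks_per_outline)
    areas_used <- c(areas_used, loop_area(lp))
  }
  # roots taper towards the apex, so a cross-section markedly smaller than
  # any slice apical to it is a corrupted cut (e.g. a partial slice through
  # the rounded cervical cap of an isosurface mesh) and is dropped
  if (length(landmarks) >= 2) {
    later_max <- rev(cummax(rev(areas_used)))
    ok <- areas_used >= 0.9 * c(later_max[-1], 0)
    if (!all(ok))
      warning(sum(!ok), " slice(s) dropped: cross-section smaller than a ",
              "more apical one (partial cut)")
    landmarks <- landmarks[ok]
  }
  n_used <- length(landmarks)
  if (n_used < 3)
    stop("fewer than 3 usable slices (", n_used, "); cannot fit a root axis")
  ax <- best_fit_line(do.call(rbind, landmarks))
  attr(ax, "n_slices") <- n_used
  ax
}

#' Axes angle (AA) between a predicted and a CBCT tooth model
#'
#' Computes the predicted-root axis (digital-model frame), maps it through
#' the frame transform into the CBCT frame, computes the CBCT-root axis,
#' and returns the angle between the two (the AA, in degrees).
#'
#' @param predicted `tooth_model` in the digital-model (scanner) frame.
#' @param cbct `tooth_model` in the CBCT frame.
#' @param frame_transform [rigid_transform()] mapping scanner to CBCT frame
#'   (typically recovered by [landmark_align()] + [icp_refine()]).
#' @param spec a [slice_plan()].
#' @return list with `tooth`, `aa_deg`, `predicted_axis` (mapped into the
#'   CBCT frame), `cbct_axis`, `n_slices`.
#' @export
measure_axes_angle <- function(predicted, cbct,
                               frame_transform = rigid_transform(),
                               spec = slice_plan()) {
  stopifnot(inherits(predicted, "tooth_model"), inherits(cbct, "tooth_model"))
  if (predicted$label != cbct$label)
    stop("FDI label mismatch: predicted ", predicted$label, " vs CBCT ",
         cbct$label)
  p_axis <- transform_line(frame_transform,
                           predicted_root_axis(predicted$root, spec))
  c_axis <- cbct_root_axis(cbct$root, spec)
  list(tooth = predicted$label,
       aa_deg = angle_between_lines(p_axis, c_axis),
       predicted_axis = p_axis,
       cbct_axis = c_axis,
       n_slices = attr(c_axis, "n_slices"))
}

#' Run the full axes-angle study over a synthetic cohort
#'
#' Per subject and arch: landmark initialization (noisy anatomical
#' landmarks emulating manual alignment) followed by trimmed ICP on the
#' crown surfaces, then [measure_axes_angle()] per tooth with the recovered
#' frame transform.  Failures are recorded and skipped; the run continues.
#'
#' @param cohort a cohort bundle from [generate_cohort()] or
#'   [read_cohort()].
#' @param spec a [slice_plan()]; per-tooth sampling seeds are derived from
#'   `spec$seed`.
#' @param icp an [icp_config()].
#' @param landmark_noise_sd Gaussian noise (mm) on the alignment landmarks,
#'   emulating manual placement error.
#' @return tibble with one row per measured tooth: `subject`, `tooth`,
#'   `arch`, `aa_deg`, `true_error_deg`, `reg_rms_mm`, `reg_rot_err_deg`,
#'   `n_slices_used`; skipped teeth are listed in attribute `skipped`.
#' @export
run_study <- function(cohort, spec = slice_plan(), icp = icp_config(),
                      landmark_noise_sd = 0.25) {
  stopifnot(inherits(cohort, "tooth_cohort"))
  rows <- list()
  skipped <- list()
  for (si in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[si]]
    for (arch_name in names(subj$arches)) {
      arch <- subj$arches[[arch_name]]
      reg <- tryCatch(
        register_arch(arch, icp, landmark_noise_sd,
                      seed = derive_seed(spec$seed, si, 777)),
        error = function(e) e)
      if (inherits(reg, "error")) {
        skipped[[length(skipped) + 1]] <- data.frame(
          subject = subj$id, arch = arch_name, tooth = NA_integer_,
          reason = conditionMessage(reg))
        next
      }
      rot_err <- if (!is.null(arch$true_transform)) {
        rotation_angle_deg(compose_transforms(
          invert_transform(arch$true_transform), reg$transform))
      } else NA_real_
      for (ti in seq_along(arch$teeth)) {
        pair <- arch$teeth[[ti]]
        res <- tryCatch({
          sp <- spec
          sp$seed <- derive_seed(spec$seed, si, pair$fdi)
          measure_axes_angle(pair$predicted, pair$cbct, reg$transform, sp)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          skipped[[length(skipped) + 1]] <- data.frame(
            subject = subj$id, arch = arch_name, tooth = pair$fdi,
            reason = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj$id, tooth = pair$fdi, arch = arch_name,
          aa_deg = res$aa_deg,
          true_error_deg = pair$true_error_deg %||% NA_real_,
          reg_rms_mm = reg$final_rms,
          reg_rot_err_deg = rot_err,
          n_slices_used = res$n_slices)
      }
    }
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "skipped") <- if (length(skipped) > 0)
    tibble::as_tibble(do.call(rbind, skipped))
  else
    tibble::tibble(subject = character(), arch = character(),
                   tooth = integer(), reason = character())
  out
}

# Register one arch: noisy landmark initialization + trimmed ICP on the
# combined crown surfaces.
register_arch <- function(arch, icp, landmark_noise_sd, seed) {
  src_lm <- arch$landmarks_scanner
  tgt_lm <- arch$landmarks_cbct
  if (landmark_noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(2 * length(src_lm), 0,
                                          landmark_noise_sd),
                                    ncol = 3))
    n1 <- nrow(src_lm)
    src_lm <- src_lm + noise[seq_len(n1), , drop = FALSE]
    tgt_lm <- tgt_lm + noise[n1 + seq_len(n1), , drop = FALSE]
  }
  init <- landmark_align(src_lm, tgt_lm)
  src_crowns <- merge_meshes(lapply(arch$teeth, function(p) p$predicted$crown))
  tgt_crowns <- merge_meshes(lapply(arch$teeth, function(p) p$cbct$crown))
  cfg <- icp
  cfg$seed <- derive_seed(icp$seed, seed)
  res <- icp_refine(src_crowns, tgt_crowns, init, cfg)
  res
}
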