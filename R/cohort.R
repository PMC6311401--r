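#' Specification of a synthetic study cohort
#'
#' Describes a cohort emulating the study design: `n_subjects` subjects,
#' the 12 permanent anterior teeth, a per-tooth-class half-normal injected
#' angular error, a random rigid misalignment between the digital-model
#' (scanner) frame and the CBCT frame per arch, and CBCT-style mesh
#' degradation by voxelization at `voxel_spacing`.
#'
#' @param n_subjects number of subjects (the emulated study used 31).
#' @param teeth FDI codes to include (default all 12 anterior teeth).
#' @param error_scale_deg half-normal scale of the injected angular error;
#'   either a single number or a named vector with entries `central`,
#'   `lateral`, `canine`.  The defaults (8.5, 11, 14.5 degrees) give
#'   per-class medians of about 8.1, 10.5 and 13.8 degrees.
#' @param misalignment_rot_deg,misalignment_trans_mm upper bounds of the
#'   random initial frame offset (rotation angle, translation magnitude).
#' @param voxel_spacing CBCT emulation voxel size in mm (0.3 matches the
#'   emulated scanner's slice thickness); `0` disables degradation.
#' @param jitter_sd vertex jitter of the predicted root (mm); `0` disables.
#' @param seed master RNG seed; everything in the cohort derives from it.
#' @param metadata_model list with `p_male`, `age_range`,
#'   `angle_class_probs` (named `I`, `II`, `III`).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 31L,
                        teeth = ANTERIOR_FDI,
                        error_scale_deg = c(central = 8.5, lateral = 11,
                                            canine = 14.5),
                        misalignment_rot_deg = 8,
                        misalignment_trans_mm = 4,
                        voxel_spacing = 0.3,
                        jitter_sd = 0.05,
                        seed = 1L,
                        metadata_model = list(
                          p_male = 10 / 31,
                          age_range = c(12, 40),
                          angle_class_probs = c(I = 0.45, II = 0.35,
                                                III = 0.20))) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  teeth <- vapply(teeth, check_fdi, integer(1))
  if (length(teeth) == 0) stop("teeth list must not be empty")
  if (any(error_scale_deg < 0)) stop("error_scale_deg must be >= 0")
  structure(list(n_subjects = n_subjects, teeth = teeth,
                 error_scale_deg = error_scale_deg,
                 misalignment_rot_deg = misalignment_rot_deg,
                 misalignment_trans_mm = misalignment_trans_mm,
                 voxel_spacing = voxel_spacing,
                 jitter_sd = jitter_sd,
                 seed = as.integer(seed),
                 metadata_model = metadata_model),
            class = "cohort_spec")
}

error_scale_for <- function(spec, label) {
  s <- spec$error_scale_deg
  if (length(s) == 1L && is.null(names(s))) return(as.double(s))
  cls <- c("central", "lateral", "canine")[label %% 10L]
  if (!is.null(names(s)) && cls %in% names(s)) return(as.double(s[[cls]]))
  as.double(s[[1]])
}

# Placement of a tooth in its arch: position on a circular arch of radius
# 22 mm, mesiodistal axis along the arch tangent, plus a small labial tilt.
arch_placement <- function(label, tilt_deg) {
  ang <- c(8, 24, 40)[label %% 10L] * pi / 180
  quadrant <- label %/% 10L
  side <- if (quadrant %in% c(1L, 4L)) -1 else 1
  lower <- quadrant >= 3L
  r <- 22
  pos <- c(r * sin(side * ang), r * cos(ang) - r, if (lower) -40 else 0)
  rz <- rotation_about_axis(c(0, 0, 1), -side * ang * 180 / pi)
  rx <- rotation_about_axis(c(1, 0, 0), tilt_deg)
  rigid_transform(rz %*% rx, pos)
}

degrade_mesh <- function(mesh, spacing) {
  vol <- voxelize(mesh, spacing)
  extract_isosurface(vol, 0.5)
}

#' Generate a synthetic study cohort
#'
#' Builds the full cohort bundle: per subject, per arch, each tooth as a
#' pair of models -- the "predicted" tooth (scanner frame, root rotated by
#' a half-normal injected error with uniform azimuth, jittered) and the
#' "CBCT" tooth (true root, optionally degraded by voxelization +
#' isosurface extraction, mapped into the CBCT frame by a random rigid
#' misalignment).  Ground truth (injected error, true frame transform,
#' true axes) is retained for evaluation.  Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `tooth_cohort`: `spec`, `metadata` (tibble), and
#'   `subjects`, each with `arches$upper` / `arches$lower` holding
#'   `true_transform`, registration landmarks, and the tooth pairs.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  mm <- spec$metadata_model
  with_seed(spec$seed, {
    metadata <- tibble::tibble(
      subject = sprintf("S%02d", seq_len(spec$n_subjects)),
      sex = ifelse(runif(spec$n_subjects) < mm$p_male, "M", "F"),
      age = round(runif(spec$n_subjects, mm$age_range[1], mm$age_range[2]), 1),
      angle_class = sample(names(mm$angle_class_probs), spec$n_subjects,
                           replace = TRUE, prob = mm$angle_class_probs))
    subjects <- vector("list", spec$n_subjects)
    for (si in seq_len(spec$n_subjects)) {
      arches <- list()
      for (arch_name in c("upper", "lower")) {
        quads <- if (arch_name == "upper") c(1L, 2L) else c(3L, 4L)
        labels <- spec$teeth[spec$teeth %/% 10L %in% quads]
        if (length(labels) == 0) next
        true_tf <- random_rigid_transform(spec$misalignment_rot_deg,
                                          spec$misalignment_trans_mm)
        teeth <- vector("list", length(labels))
        lm_s <- matrix(NA_real_, 2 * length(labels), 3)
        for (ti in seq_along(labels)) {
          lab <- labels[ti]
          base <- default_shape_params(lab)
          params <- tooth_shape_params(
            root_length = base$root_length * runif(1, 0.92, 1.08),
            cervical_radius_mesiodistal =
              base$cervical_radius_mesiodistal * runif(1, 0.9, 1.1),
            cervical_radius_labiolingual =
              base$cervical_radius_labiolingual * runif(1, 0.9, 1.1),
            taper_exponent = base$taper_exponent,
            apical_curve_deg = min(30, base$apical_curve_deg *
                                     runif(1, 0.6, 1.4)),
            crown_height = base$crown_height * runif(1, 0.95, 1.05),
            mesh_resolution = base$mesh_resolution)
          tooth <- generate_tooth(lab, params,
                                  seed = derive_seed(spec$seed, si, lab))
          scale <- error_scale_for(spec, lab)
          err <- if (scale > 0) min(abs(rnorm(1, 0, scale)), 45) else 0
          azim <- runif(1, 0, 360)
          placement <- arch_placement(lab, tilt_deg = rnorm(1, 5, 3))
          predicted <- transform_tooth(
            placement,
            perturb_predicted_root(tooth, err, azim,
                                   seed = derive_seed(spec$seed, si, lab, 2),
                                   jitter_sd = spec$jitter_sd))
          cbct <- transform_tooth(compose_transforms(true_tf, placement),
                                  tooth)
          if (spec$voxel_spacing > 0) {
            cbct$crown <- degrade_mesh(cbct$crown, spec$voxel_spacing)
            cbct$root <- degrade_mesh(cbct$root, spec$voxel_spacing)
          }
          tip_local <- c(0, 0, tooth$params$crown_height)
          lm_s[2 * ti - 1, ] <- apply_transform(placement, c(0, 0, 0))
          lm_s[2 * ti, ] <- apply_transform(placement, tip_local)
          teeth[[ti]] <- list(fdi = lab, predicted = predicted, cbct = cbct,
                              true_error_deg = err, azimuth_deg = azim)
        }
        arches[[arch_name]] <- list(
          true_transform = true_tf,
          landmarks_scanner = lm_s,
          landmarks_cbct = apply_transform(true_tf, lm_s),
          teeth = teeth)
      }
      subjects[[si]] <- list(id = metadata$subject[si], arches = arches)
    }
    structure(list(spec = spec, metadata = metadata, subjects = subjects),
              class = "tooth_cohort")
  })
}

#' @export
print.tooth_cohort <- function(x, ...) {
  np <- sum(vapply(x$subjects, function(s)
    sum(vapply(s$arches, function(a) length(a$teeth), integer(1))),
    integer(1)))
  cat("<tooth_cohort> ", length(x$subjects), " subjects, ", np,
      " tooth pairs\n", sep = "")
  invisible(x)
}

#' Write a cohort to a directory tree
#'
#' Lays the cohort out as `metadata.csv`, `manifest.csv` and binary STL
#' files (one per tooth, frame and part).  The manifest carries the
#' ground-truth injected error, the per-arch true frame transform (12
#' numbers, row-major 3 x 4), and the cervix/apex anchors.
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, force = FALSE) {
  stopifnot(inherits(cohort, "tooth_cohort"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stop("output directory ", dir, " exists and is not empty; use force = TRUE")
  dir.create(file.path(dir, "stl"), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  rows <- list()
  for (subj in cohort$subjects) {
    for (arch_name in names(subj$arches)) {
      arch <- subj$arches[[arch_name]]
      tf <- arch$true_transform
      tf12 <- as.vector(t(cbind(tf$rotation, tf$translation)))
      for (pair in arch$teeth) {
        for (frame in c("scanner", "cbct")) {
          model <- if (frame == "scanner") pair$predicted else pair$cbct
          for (part in c("crown", "root")) {
            fn <- sprintf("%s_%d_%s_%s.stl", subj$id, pair$fdi, frame, part)
            write_stl(model[[part]], file.path(dir, "stl", fn))
            rows[[length(rows) + 1]] <- data.frame(
              subject = subj$id, tooth = pair$fdi, arch = arch_name,
              frame = frame, part = part, file = file.path("stl", fn),
              true_error_deg = pair$true_error_deg,
              cervix_x = model$cervix_center[1],
              cervix_y = model$cervix_center[2],
              cervix_z = model$cervix_center[3],
              apex_x = model$apex[1], apex_y = model$apex[2],
              apex_z = model$apex[3],
              crown_height = model$params$crown_height,
              t(setNames(tf12, paste0("t", rep(1:3, each = 4), 1:4))))
          }
        }
      }
    }
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory back into a bundle
#'
#' Inverse of [write_cohort()]; registration landmarks (cervix center and
#' incisal tip per tooth) are reconstructed from the stored anchors and
#' crown meshes.
#'
#' @param dir a directory written by [write_cohort()].
#' @return a `tooth_cohort` bundle.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  meta_path <- file.path(dir, "metadata.csv")
  for (p in c(man_path, meta_path))
    if (!file.exists(p)) stop("missing cohort file: ", p)
  manifest <- read.csv(man_path, stringsAsFactors = FALSE)
  metadata <- tibble::as_tibble(read.csv(meta_path, stringsAsFactors = FALSE))
  subjects <- list()
  crown_tip <- function(crown, cervix, apex) {
    ax <- normalize(cervix - apex)
    s <- as.vector(sweep(crown$vertices, 2, cervix) %*% ax)
    crown$vertices[which.max(s), ]
  }
  for (sid in unique(manifest$subject)) {
    ms <- manifest[manifest$subject == sid, ]
    arches <- list()
    for (arch_name in unique(ms$arch)) {
      ma <- ms[ms$arch == arch_name, ]
      tfrow <- ma[1, paste0("t", rep(1:3, each = 4), 1:4)]
      M <- matrix(as.double(tfrow), 3, 4, byrow = TRUE)
      true_tf <- rigid_transform(M[, 1:3], M[, 4])
      teeth <- list()
      lm_s <- NULL; lm_t <- NULL
      for (fdi in unique(ma$tooth)) {
        mt <- ma[ma$tooth == fdi, ]
        if (!all(file.exists(file.path(dir, mt$file)))) {
          warning("subject ", sid, " tooth ", fdi,
                  ": mesh file(s) missing; tooth skipped")
          next
        }
        get_model <- function(frame) {
          parts <- lapply(c("crown", "root"), function(part) {
            r <- mt[mt$frame == frame & mt$part == part, ]
            if (nrow(r) != 1) stop("manifest missing ", frame, " ", part,
                                   " for subject ", sid, " tooth ", fdi)
            list(mesh = read_stl(file.path(dir, r$file)), row = r)
          })
          r <- parts[[1]]$row
          structure(list(label = as.integer(fdi),
                         crown = parts[[1]]$mesh, root = parts[[2]]$mesh,
                         cervix_center = c(r$cervix_x, r$cervix_y, r$cervix_z),
                         apex = c(r$apex_x, r$apex_y, r$apex_z),
                         true_axis = NULL,
                         params = list(crown_height = r$crown_height)),
                    class = "tooth_model")
        }
        predicted <- get_model("scanner")
        cbct <- get_model("cbct")
        lm_s <- rbind(lm_s, predicted$cervix_center,
                      crown_tip(predicted$crown, predicted$cervix_center,
                                predicted$apex))
        lm_t <- rbind(lm_t, cbct$cervix_center,
                      crown_tip(cbct$crown, cbct$cervix_center, cbct$apex))
        teeth[[length(teeth) + 1]] <- list(
          fdi = as.integer(fdi), predicted = predicted, cbct = cbct,
          true_error_deg = mt$true_error_deg[1])
      }
      if (length(teeth) == 0) next
      arches[[arch_name]] <- list(true_transform = true_tf,
                                  landmarks_scanner = unname(lm_s),
                                  landmarks_cbct = unname(lm_t),
                                  teeth = teeth)
    }
    subjects[[length(subjects) + 1]] <- list(id = sid, arches = arches)
  }
  structure(list(spec = NULL, metadata = metadata, subjects = subjects),
            class = "tooth_cohort")
}
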