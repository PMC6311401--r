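test_that("rigid transforms validate, compose and invert correctly", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  R <- rootaxis:::rotation_about_axis(c(0, 0, 1), 30)
  tf <- rigid_transform(R, c(1, 2, 3))
  inv <- invert_transform(tf)
  comp <- compose_transforms(inv, tf)
  expect_lt(rotation_angle_deg(comp), 1e-9)
  expect_lt(rootaxis:::vnorm(comp$translation), 1e-9)
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(inv, apply_transform(tf, p)), p,
               tolerance = 1e-12)
})

test_that("landmark alignment recovers an exact rigid transform", {
  set.seed(11)
  src <- matrix(rnorm(15, sd = 5), ncol = 3)
  R <- rootaxis:::rotation_about_axis(c(0, 0, 1), 30)
  tf <- rigid_transform(R, c(1, 2, 3))
  rec <- landmark_align(src, apply_transform(tf, src))
  expect_lt(max(abs(rec$rotation - tf$rotation)), 1e-9)
  expect_lt(max(abs(rec$translation - tf$translation)), 1e-9)

  ident <- landmark_align(src, src)
  expect_lt(rotation_angle_deg(ident), 1e-9)
  expect_lt(rootaxis:::vnorm(ident$translation), 1e-9)
})

test_that("landmark alignment rejects degenerate landmark sets", {
  line_pts <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(landmark_align(line_pts, line_pts + 1), "collinear")
  expect_error(landmark_align(matrix(rnorm(12), 4), matrix(rnorm(9), 3)),
               "differ")
  expect_error(landmark_align(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
})

test_that("Kabsch residual is the optimum over random rigid transforms", {
  set.seed(21)
  src <- matrix(rnorm(12, sd = 4), ncol = 3)
  tgt <- apply_transform(rigid_transform(
    rootaxis:::rotation_about_axis(rnorm(3), 25), c(2, -1, 0.5)), src) +
    matrix(rnorm(12, sd = 0.1), ncol = 3)
  best <- landmark_align(src, tgt)
  rss <- function(tf) sum((apply_transform(tf, src) - tgt)^2)
  r0 <- rss(best)
  for (i in 1:1000) {
    cand <- rootaxis:::random_rigid_transform(180, 10)
    expect_gte(rss(cand), r0 - 1e-9)
  }
})

test_that("trimmed ICP recovers a small known offset from identity", {
  arch <- crown_arch_mesh(c(11, 12, 21))
  tf <- rigid_transform(rootaxis:::rotation_about_axis(c(0.3, 1, 0.2), 2),
                        c(0.3, -0.2, 0.3))
  tgt <- rootaxis:::transform_mesh(tf, arch)
  res <- icp_refine(arch, tgt, rigid_transform(),
                    icp_config(source_sample_count = 2000, seed = 3))
  delta <- compose_transforms(invert_transform(tf), res$transform)
  expect_lt(rotation_angle_deg(delta), 0.1)
  expect_lt(rootaxis:::vnorm(delta$translation), 0.05)
})

test_that("ICP at the exact transform converges immediately", {
  arch <- crown_arch_mesh(c(11, 21))
  tf <- rigid_transform(rootaxis:::rotation_about_axis(c(0, 0, 1), 5),
                        c(1, 1, 0))
  tgt <- rootaxis:::transform_mesh(tf, arch)
  res <- icp_refine(arch, tgt, tf, icp_config(seed = 2))
  expect_lte(res$iterations, 2)
  expect_lt(res$final_rms, 1e-6)
})

test_that("trimming tolerates partial overlap (crowns vs crowns+roots)", {
  labels <- c(11, 12, 13)
  teeth <- lapply(labels, function(l) generate_tooth(l))
  place <- lapply(teeth, function(t)
    rootaxis:::arch_placement(t$label, 6))
  crowns <- rootaxis:::merge_meshes(mapply(function(t, p)
    rootaxis:::transform_mesh(p, t$crown), teeth, place, SIMPLIFY = FALSE))
  full <- rootaxis:::merge_meshes(mapply(function(t, p)
    rootaxis:::merge_meshes(list(rootaxis:::transform_mesh(p, t$crown),
                                 rootaxis:::transform_mesh(p, t$root))),
    teeth, place, SIMPLIFY = FALSE))
  tf <- rigid_transform(rootaxis:::rotation_about_axis(c(1, 0.5, 0), 4),
                        c(1, -0.5, 1))
  tgt <- rootaxis:::transform_mesh(tf, full)
  res <- icp_refine(crowns, tgt, rigid_transform(),
                    icp_config(trim_fraction = 0.9, seed = 5))
  delta <- compose_transforms(invert_transform(tf), res$transform)
  expect_lt(rotation_angle_deg(delta), 0.5)
})

test_that("kept-pair RMS is non-increasing across ICP iterations", {
  arch <- crown_arch_mesh(c(11, 12))
  tf <- rootaxis:::random_rigid_transform(6, 3)
  set.seed(31)
  tgt <- rootaxis:::transform_mesh(tf, arch)
  res <- icp_refine(arch, tgt, rigid_transform(), icp_config(seed = 7))
  expect_true(all(diff(res$rms_history) <= 1e-9))
})

test_that("disjoint frames are rejected with advice", {
  arch <- crown_arch_mesh(c(11))
  far <- rootaxis:::transform_mesh(rigid_transform(diag(3), c(500, 0, 0)),
                                   arch)
  expect_error(icp_refine(arch, far, rigid_transform(), icp_config()),
               "initial")
})
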