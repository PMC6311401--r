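test_that("a straight construction has an exact ground-truth axis", {
  p <- tooth_shape_params(apical_curve_deg = 0)
  t0 <- generate_tooth(11, p, seed = 1)
  expect_lt(sum(abs(abs(t0$true_axis$direction) - c(0, 0, 1))), 1e-9)
})

test_that("tooth generation is deterministic and watertight", {
  a <- generate_tooth(32, seed = 4)
  b <- generate_tooth(32, seed = 4)
  expect_identical(a$root$vertices, b$root$vertices)
  expect_identical(a$crown$faces, b$crown$faces)
  expect_false(identical(a$root$vertices,
                         generate_tooth(32, seed = 5)$root$vertices))
  expect_equal(rootaxis:::open_edge_count(a$root), 0)
  expect_equal(rootaxis:::open_edge_count(a$crown), 0)
})

test_that("root length and cervical-margin sharing hold for all classes", {
  for (lab in c(11, 12, 13, 31, 32, 33)) {
    t <- generate_tooth(lab, seed = 2)
    len <- rootaxis:::vnorm(t$apex - t$cervix_center)
    expect_gt(len, 8)
    expect_lt(len, 30)
    # crown base ring must coincide with the root's cervical ring
    rb <- t$root$vertices[abs(t$root$vertices[, 3]) < 1e-9, , drop = FALSE]
    cb <- t$crown$vertices[abs(t$crown$vertices[, 3]) < 1e-9, , drop = FALSE]
    or <- order(rb[, 1], rb[, 2]); oc <- order(cb[, 1], cb[, 2])
    expect_lt(max(abs(rb[or, ] - cb[oc, ])), 0.1)
  }
})

test_that("surface area converges as ring resolution doubles", {
  p24 <- tooth_shape_params(taper_exponent = 1, apical_curve_deg = 0,
                            mesh_resolution = 24)
  p48 <- tooth_shape_params(taper_exponent = 1, apical_curve_deg = 0,
                            mesh_resolution = 48)
  a24 <- sum(rootaxis:::face_areas(generate_tooth(11, p24)$root))
  a48 <- sum(rootaxis:::face_areas(generate_tooth(11, p48)$root))
  expect_lt(abs(a48 / a24 - 1), 0.01)
})

test_that("invalid labels and parameters are rejected", {
  expect_error(generate_tooth(14), "anterior")
  expect_error(generate_tooth(8), "anterior")
  expect_error(tooth_shape_params(root_length = -1))
  expect_error(tooth_shape_params(taper_exponent = 0.2))
  expect_error(tooth_shape_params(apical_curve_deg = 45))
})

test_that("zero perturbation with jitter off is the identity", {
  t0 <- generate_tooth(21, seed = 1)
  tp <- perturb_predicted_root(t0, 0, 0, jitter_sd = 0)
  expect_equal(tp$root$vertices, t0$root$vertices, tolerance = 1e-12)
  expect_identical(tp$crown, t0$crown)
})

test_that("perturbation injects the requested angle", {
  t0 <- generate_tooth(21, seed = 1)
  tp <- perturb_predicted_root(t0, 10, 30, jitter_sd = 0)
  # exact on the carried ground-truth axis
  expect_equal(angle_between_lines(tp$true_axis, t0$true_axis), 10,
               tolerance = 1e-9)
  # and recovered by the axis estimator from the rotated mesh
  est <- predicted_root_axis(tp$root, slice_plan(seed = 8))
  expect_equal(angle_between_lines(est, t0$true_axis), 10, tolerance = 0.2)
})

test_that("opposite azimuths compose to twice the injected angle", {
  t0 <- generate_tooth(21, seed = 1)
  ta <- perturb_predicted_root(t0, 10, 0, jitter_sd = 0)
  tb <- perturb_predicted_root(t0, 10, 180, jitter_sd = 0)
  ea <- predicted_root_axis(ta$root, slice_plan(seed = 3))
  eb <- predicted_root_axis(tb$root, slice_plan(seed = 3))
  expect_equal(angle_between_lines(ea, eb), 20, tolerance = 0.4)
  expect_error(perturb_predicted_root(t0, 60), "45")
})
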