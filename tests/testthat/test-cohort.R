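# A single undegraded 31-subject cohort shared by the cohort-level checks;
# voxel degradation is exercised separately (test-voxel.R and the
# end-to-end acceptance suite).
clean_cohort <- local({
  ch <- NULL
  function() {
    if (is.null(ch))
      ch <<- generate_cohort(cohort_spec(n_subjects = 31, voxel_spacing = 0,
                                         jitter_sd = 0, seed = 101))
    ch
  }
})

test_that("31 subjects x 12 anterior teeth yield 372 tooth pairs", {
  ch <- clean_cohort()
  n_pairs <- sum(vapply(ch$subjects, function(s)
    sum(vapply(s$arches, function(a) length(a$teeth), integer(1))),
    integer(1)))
  expect_equal(n_pairs, 372)
  expect_equal(nrow(ch$metadata), 31)
  expect_named(ch$metadata, c("subject", "sex", "age", "angle_class"))
})

test_that("injected errors follow the configured half-normal model", {
  ch <- clean_cohort()
  errs <- unlist(lapply(ch$subjects, function(s)
    lapply(s$arches, function(a)
      vapply(a$teeth, function(p) p$true_error_deg, numeric(1)))))
  scales <- unlist(lapply(ch$subjects, function(s)
    lapply(s$arches, function(a)
      vapply(a$teeth, function(p)
        rootaxis:::error_scale_for(ch$spec, p$fdi), numeric(1)))))
  expect_length(errs, 372)
  z <- errs / scales
  # standardized half-normal mean sqrt(2/pi), within 3 standard errors
  se <- sqrt(1 - 2 / pi) / sqrt(length(z))
  expect_lt(abs(mean(z) - sqrt(2 / pi)), 3 * se)
})

test_that("zero error scale injects exactly zero errors", {
  ch <- generate_cohort(cohort_spec(n_subjects = 1, teeth = c(11, 21),
                                    error_scale_deg = 0, voxel_spacing = 0,
                                    seed = 3))
  errs <- vapply(ch$subjects[[1]]$arches$upper$teeth,
                 function(p) p$true_error_deg, numeric(1))
  expect_identical(errs, c(0, 0))
})

test_that("cohorts are reproducible bit-for-bit from their seed", {
  spec <- cohort_spec(n_subjects = 2, teeth = c(11, 31),
                      voxel_spacing = 0, seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(spec), d1)
  write_cohort(generate_cohort(spec), d2)
  for (f in c("manifest.csv", "metadata.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  stl1 <- sort(list.files(file.path(d1, "stl")))
  expect_identical(stl1, sort(list.files(file.path(d2, "stl"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "stl", stl1[1]))),
                   unname(tools::md5sum(file.path(d2, "stl", stl1[1]))))
})

test_that("a cohort directory round-trips through write and read", {
  spec <- cohort_spec(n_subjects = 2, teeth = c(11, 21),
                      voxel_spacing = 0, jitter_sd = 0, seed = 23)
  ch <- generate_cohort(spec)
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_equal(length(back$subjects), 2)
  pair0 <- ch$subjects[[1]]$arches$upper$teeth[[1]]
  pair1 <- back$subjects[[1]]$arches$upper$teeth[[1]]
  expect_equal(pair1$fdi, pair0$fdi)
  expect_equal(pair1$true_error_deg, pair0$true_error_deg, tolerance = 1e-6)
  expect_equal(nrow(pair1$predicted$root$faces),
               nrow(pair0$predicted$root$faces))
  expect_equal(pair1$cbct$cervix_center, pair0$cbct$cervix_center,
               tolerance = 1e-6)
  tf0 <- ch$subjects[[1]]$arches$upper$true_transform
  tf1 <- back$subjects[[1]]$arches$upper$true_transform
  expect_lt(rotation_angle_deg(compose_transforms(invert_transform(tf0),
                                                  tf1)), 1e-4)
})

test_that("the full pipeline recovers injected errors on a clean cohort", {
  ch <- clean_cohort()
  sub <- ch
  sub$subjects <- ch$subjects[1:8]
  aa <- run_study(sub, slice_plan(seed = 2), icp_config(seed = 2))
  expect_equal(nrow(aa), 8 * 12)
  dev <- abs(aa$aa_deg - aa$true_error_deg)
  expect_gte(mean(dev < 0.5), 0.95)
})

test_that("cohort specs validate their fields", {
  expect_error(cohort_spec(n_subjects = 0), "n_subjects")
  expect_error(cohort_spec(teeth = integer(0)), "empty")
  expect_error(cohort_spec(teeth = c(11, 16)), "anterior")
  expect_error(cohort_spec(error_scale_deg = -1), "error_scale_deg")
})
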