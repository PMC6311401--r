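test_that("paired sample-size formula reproduces reference cases", {
  expect_identical(dupont_plummer_n(s = 5, d = 3), 24L)
  expect_identical(dupont_plummer_n(s = 5, d = 5), 10L)
  expect_identical(dupont_plummer_n(s = 5, d = 500), 2L)  # floor rule
  expect_error(dupont_plummer_n(s = -1, d = 1))
})

test_that("sample size is monotone in s, d and power", {
  grid_s <- 2:8
  grid_d <- 1:5
  for (d in grid_d) {
    ns <- vapply(grid_s, function(s) dupont_plummer_n(s, d), integer(1))
    expect_true(all(diff(ns) >= 0))
  }
  for (s in grid_s) {
    nd <- vapply(grid_d, function(d) dupont_plummer_n(s, d), integer(1))
    expect_true(all(diff(nd) <= 0))
  }
  expect_gte(dupont_plummer_n(5, 3, power = 0.9), dupont_plummer_n(5, 3))
})

test_that("shapiro_wilk validates its domain", {
  expect_error(shapiro_wilk(c(1, 1, 1, 1)), "equal")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  out <- shapiro_wilk(c(2.1, 3.5, 1.2, 4.4, 2.8))
  expect_true(out$statistic > 0 && out$statistic <= 1)
})

test_that("mann_whitney matches hand-computed exact cases", {
  out <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 2 / 6, tolerance = 1e-12)
  expect_true(out$exact)

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 9 / 2)
  expect_gt(same$p_value, 0.99)

  shift <- mann_whitney(1001:1005, 1:5)
  expect_equal(shift$p_value, 2 / 252, tolerance = 1e-12)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals the exhaustive permutation oracle", {
  perm_oracle <- function(a, b) {
    pooled <- c(a, b)
    na <- length(a)
    u_of <- function(idx) {
      x <- pooled[idx]; y <- pooled[-idx]
      sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    us <- apply(utils::combn(length(pooled), na), 2, u_of)
    u_obs <- u_of(seq_len(na))
    p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
    min(1, p)
  }
  set.seed(202)
  for (i in 1:100) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    repeat {
      a <- round(rnorm(na, sd = 5), 3)
      b <- round(rnorm(nb, sd = 5), 3)
      if (!anyDuplicated(c(a, b))) break
    }
    out <- mann_whitney(a, b)
    expect_true(out$exact)
    expect_equal(out$p_value, perm_oracle(a, b), tolerance = 1e-9)
  }
})

test_that("kruskal_wallis reproduces the closed-form two-group case", {
  out <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(out$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(out$df, 1)
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(33)
  for (i in 1:20) {
    a <- rnorm(sample(4:9, 1))
    b <- rnorm(sample(4:9, 1))
    H <- kruskal_wallis(list(a, b))$statistic
    na <- length(a); nb <- length(b); N <- na + nb
    U <- mann_whitney(a, b)$statistic
    z <- (U - na * nb / 2) / sqrt(na * nb * (N + 1) / 12)
    expect_equal(H, z^2, tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment multiplies, caps and preserves order", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(c(0.9, 0.9)), c(1, 1))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- runif(10)
  expect_true(all(bonferroni_adjust(p) >= p))
})

test_that("paired t-test matches hand computation and rejects degeneracy", {
  out <- paired_t(c(1, 0, 2), c(0, 0, 0))
  expect_equal(out$statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  expect_error(paired_t(1:3, 1:3), "zero variance")
  expect_error(paired_t(1:3, 1:4), "length")
})

test_that("bland_altman matches hand computation and its invariants", {
  out <- bland_altman(c(1, -1, 2, 0, 3), c(0, 0, 0, 0, 0))
  expect_equal(out$bias, 1)
  expect_equal(out$sd_diff, sqrt(2.5), tolerance = 1e-12)
  expect_equal(out$loa_lower, 1 - 1.96 * sqrt(2.5), tolerance = 1e-12)

  same <- bland_altman(1:5, 1:5)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))

  offset <- bland_altman(1:5 + 5, 1:5)
  expect_equal(offset$bias, 5)
  expect_equal(offset$sd_diff, 0)

  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(10)
    ba <- bland_altman(x, y)
    expect_equal(ba$loa_lower, ba$bias - 1.96 * ba$sd_diff)
    expect_equal(ba$loa_upper, ba$bias + 1.96 * ba$sd_diff)
    expect_lte(ba$loa_lower, ba$bias)
    expect_gte(ba$loa_upper, ba$bias)
  }
})

simulate_aa_table <- function(n_subjects = 31, seed = 1) {
  set.seed(seed)
  teeth <- c(11, 12, 13, 21, 22, 23, 31, 32, 33, 41, 42, 43)
  meta <- tibble::tibble(
    subject = sprintf("S%02d", seq_len(n_subjects)),
    sex = sample(c("M", "F"), n_subjects, replace = TRUE,
                 prob = c(10, 21) / 31),
    age = runif(n_subjects, 12, 40),
    angle_class = sample(c("I", "II", "III"), n_subjects, replace = TRUE))
  rec <- expand.grid(subject = meta$subject, tooth = teeth,
                     stringsAsFactors = FALSE)
  rec$aa_deg <- abs(rnorm(nrow(rec), 0, 10))
  list(records = tibble::as_tibble(rec), metadata = meta)
}

test_that("summarize_aa produces one summary row per tooth", {
  sim <- simulate_aa_table(31, seed = 55)
  out <- summarize_aa(sim$records, sim$metadata)
  expect_equal(nrow(out$tooth_summary), 12)
  expect_true(all(out$tooth_summary$n == 31))
  s <- out$tooth_summary
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$max))
  expect_true(all(c("shapiro_wilk", "sex_mann_whitney",
                    "angle_class_kruskal_wallis") %in%
                    out$group_tests$test))
})

test_that("summarize_aa reports missing metadata columns by name", {
  sim <- simulate_aa_table(10, seed = 9)
  expect_error(summarize_aa(sim$records, sim$metadata[, c("subject", "sex")]),
               "age")
  expect_error(summarize_aa(sim$records[, c("subject", "tooth")],
                            sim$metadata), "aa_deg")
})

test_that("a null cohort shows no significant group differences", {
  sim <- simulate_aa_table(31, seed = 77)
  sim$records$aa_deg <- abs(rnorm(nrow(sim$records), 0, 0.2))
  out <- summarize_aa(sim$records, sim$metadata)
  expect_true(all(out$tooth_summary$median < 1))
  grp <- out$group_tests[out$group_tests$test != "shapiro_wilk", ]
  expect_true(all(grp$p_adjusted > 0.05, na.rm = TRUE))
})
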