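#' Dupont-Plummer paired sample size
#'
#' Smallest integer n satisfying the paired-design relation
#' \deqn{n \ge (s/d)^2 \, (t_{\alpha/2,\,n-1} + t_{\beta,\,n-1})^2}
#' where `s` is the standard deviation of within-pair differences and `d`
#' the minimum difference to detect.  Solved by iterating the Student-t
#' fixed point from the normal-approximation start, with a floor of n = 2.
#'
#' @param s estimated standard deviation of differences (degrees); > 0.
#' @param d minimum detectable difference (degrees); > 0.
#' @param alpha two-sided type-I error rate.
#' @param power desired power (1 - beta).
#' @return required total sample size (integer).
#' @export
dupont_plummer_n <- function(s, d, alpha = 0.05, power = 0.80) {
  stopifnot(s > 0, d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  ratio2 <- (s / d)^2
  za <- -qnorm(alpha / 2)
  zb <- qnorm(power)
  # t-quantile requirement for a candidate n (decreasing in n, so the
  # feasibility condition n >= f(n) is monotone and the smallest feasible n
  # is well defined)
  f <- function(n) {
    k <- max(n - 1, 1)
    ratio2 * (qt(1 - alpha / 2, df = k) + qt(power, df = k))^2
  }
  n <- max(2, floor(ratio2 * (za + zb)^2) - 2)
  for (i in seq_len(100000)) {
    if (n >= f(n)) {
      # walk back in case the start overshot the smallest feasible n
      while (n > 2 && (n - 1) >= f(n - 1)) n <- n - 1
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop("sample size search did not converge")
}

#' Shapiro-Wilk normality test
#'
#' Royston-parameterized W statistic and p-value (delegates to
#' [stats::shapiro.test()]), with explicit domain checks: 3 <= n <= 5000
#' and non-zero variance.
#'
#' @param values numeric sample.
#' @return list with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.double(values)
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000; n = ", n)
  if (stats::var(values) == 0) stop("all values are equal; W is undefined")
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Mann-Whitney U test
#'
#' U counts pairs with `a_i > b_j` (ties counted 1/2).  The p-value is
#' exact (distribution of U under the permutation null) when the pooled
#' sample size is at most 12 and there are no ties, otherwise a normal
#' approximation with tie correction and continuity correction is used --
#' the same convention as common statistical packages.  Delegates to
#' [stats::wilcox.test()].
#'
#' @param a,b numeric samples (both non-empty).
#' @return list with `statistic` (U for `a` vs `b`) and `p_value`
#'   (two-sided).
#' @export
mann_whitney <- function(a, b) {
  a <- as.double(a); b <- as.double(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution
#' (k - 1 df); delegates to [stats::kruskal.test()].  Errors when every
#' observation is identical (H undefined under full ties).
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups, >= 3
#'   observations in total).
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, as.double)
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need at least 2 non-empty groups")
  x <- unlist(groups)
  if (length(x) < 3) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1)
    stop("all values identical; H is undefined under full ties")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(x, g)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1, preserving
#' input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(pvalues) {
  pvalues <- as.double(pvalues)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "bonferroni")
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on differences `d = x - y`, df = n-1;
#' used for assessing systematic error between repeated measurements.
#'
#' @param x,y paired numeric samples of equal length (n >= 2).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
paired_t <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y))
    stop("x and y must have the same length (", length(x), " vs ",
         length(y), ")")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  if (stats::var(d) == 0)
    stop("differences have zero variance; t is undefined")
  ht <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Bland-Altman limits of agreement
#'
#' Classical agreement analysis of paired measurements: bias = mean of the
#' differences `x - y`, `sd_diff` their sample standard deviation (n - 1
#' denominator), and 95% limits of agreement bias +/- 1.96 sd_diff.
#'
#' @param x,y paired numeric samples of equal length (n >= 2).
#' @return object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `n`.
#' @export
bland_altman <- function(x, y) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y))
    stop("x and y must have the same length (", length(x), " vs ",
         length(y), ")")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_lower = bias - 1.96 * sd_diff,
                 loa_upper = bias + 1.96 * sd_diff,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% LoA [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Per-tooth summary and group comparisons of axes angles
#'
#' Produces the descriptive table (n, median, min, max, quartiles per
#' tooth; quartiles by linear interpolation between order statistics) and
#' the group-comparison battery: a Shapiro-Wilk normality screen per tooth,
#' sex comparison per tooth (Mann-Whitney, Bonferroni-adjusted across
#' teeth), Angle-class comparison per tooth (Kruskal-Wallis,
#' Bonferroni-adjusted), and an age comparison on a median split
#' (Mann-Whitney, Bonferroni-adjusted).
#'
#' @param records tibble with at least `subject`, `tooth`, `aa_deg` (e.g.
#'   from [run_study()]).
#' @param metadata tibble with `subject`, `sex`, `age`, `angle_class`.
#' @param pool_sex if `TRUE`, the sex comparison additionally pools all
#'   teeth into one test (reported as tooth `NA`).
#' @return list with `tooth_summary` (tibble), `group_tests` (tibble:
#'   test, tooth, statistic, p_raw, p_adjusted), and `quartile_rule`.
#' @export
summarize_aa <- function(records, metadata, pool_sex = FALSE) {
  need_rec <- c("subject", "tooth", "aa_deg")
  miss <- setdiff(need_rec, names(records))
  if (length(miss) > 0)
    stop("records is missing columns: ", paste(miss, collapse = ", "))
  need_meta <- c("subject", "sex", "age", "angle_class")
  miss <- setdiff(need_meta, names(metadata))
  if (length(miss) > 0)
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("records table is empty")
  dat <- dplyr::inner_join(tibble::as_tibble(records),
                           tibble::as_tibble(metadata), by = "subject")

  tooth_summary <- dat |>
    dplyr::group_by(tooth) |>
    dplyr::summarise(n = dplyr::n(),
                     median = median(aa_deg),
                     min = min(aa_deg),
                     max = max(aa_deg),
                     q1 = quantile(aa_deg, 0.25, names = FALSE),
                     q3 = quantile(aa_deg, 0.75, names = FALSE),
                     .groups = "drop") |>
    dplyr::arrange(tooth)

  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  tests <- list()
  add <- function(test, tooth, statistic, p)
    tests[[length(tests) + 1]] <<- data.frame(
      test = test, tooth = tooth, statistic = statistic, p_raw = p)

  med_age <- median(metadata$age)
  for (tt in sort(unique(dat$tooth))) {
    sub <- dat[dat$tooth == tt, ]
    sw <- safe(shapiro_wilk(sub$aa_deg))
    if (!is.null(sw)) add("shapiro_wilk", tt, sw$statistic, sw$p_value)
    mw <- safe(mann_whitney(sub$aa_deg[sub$sex == "M"],
                            sub$aa_deg[sub$sex == "F"]))
    if (!is.null(mw)) add("sex_mann_whitney", tt, mw$statistic, mw$p_value)
    kw <- safe(kruskal_wallis(split(sub$aa_deg, sub$angle_class)))
    if (!is.null(kw)) add("angle_class_kruskal_wallis", tt, kw$statistic,
                          kw$p_value)
    aw <- safe(mann_whitney(sub$aa_deg[sub$age <= med_age],
                            sub$aa_deg[sub$age > med_age]))
    if (!is.null(aw)) add("age_median_split_mann_whitney", tt, aw$statistic,
                          aw$p_value)
  }
  if (pool_sex) {
    mw <- safe(mann_whitney(dat$aa_deg[dat$sex == "M"],
                            dat$aa_deg[dat$sex == "F"]))
    if (!is.null(mw)) add("sex_mann_whitney_pooled", NA_integer_,
                          mw$statistic, mw$p_value)
  }
  group_tests <- tibble::as_tibble(do.call(rbind, tests))
  group_tests <- group_tests |>
    dplyr::group_by(test) |>
    dplyr::mutate(p_adjusted = ifelse(test == "shapiro_wilk", p_raw,
                                      bonferroni_adjust(p_raw))) |>
    dplyr::ungroup()

  list(tooth_summary = tooth_summary, group_tests = group_tests,
       quartile_rule = "linear interpolation between order statistics (R type 7)")
}
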