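test_that("odds and odds ratios follow the segment-count definition", {
  r <- odds_and_or(c(38, 6), c(42, 22))
  expect_equal(r$odds_a, 38 / 6)
  expect_equal(r$odds_b, 42 / 22)
  expect_equal(round(r$odds_ratio, 1), 3.3)
  expect_lt(r$ci_low, r$ci_high)
  expect_equal(r$band, "large")
  # self-comparison and reciprocity
  expect_equal(odds_and_or(c(1, 1), c(1, 1))$odds_ratio, 1)
  ab <- odds_and_or(c(21, 19), c(9, 87))$odds_ratio
  ba <- odds_and_or(c(9, 87), c(21, 19))$odds_ratio
  expect_equal(ab * ba, 1)
  expect_equal(ab, (21 / 19) / (9 / 87), tolerance = 1e-12)
  expect_error(odds_and_or(c(5, 0), c(1, 1)), "continuity")
  expect_silent(odds_and_or(c(5, 0), c(1, 1), continuity = TRUE))
})

test_that("basic bootstrap CIs behave on degenerate and strong effects", {
  cfg <- gm_config(bootstrap_iterations = 2000, rng_seed = 3)
  const <- bootstrap_mean_diff_ci(rep(2, 5), rep(2, 5), cfg)
  expect_equal(const$estimate[1], 0)
  expect_equal(const$low[1], 0)
  expect_equal(const$high[1], 0)
  expect_false(const$significant[1])
  expect_equal(nrow(const), 1L)  # cascade stops immediately
  set.seed(8)
  strong <- bootstrap_mean_diff_ci(rnorm(30, 1, 0.1), rnorm(30, 0, 0.1), cfg)
  expect_true(strong$significant[1])
  expect_true(strong$low[1] > 0)
  # escalation covers the stated levels in order, stopping by 99.999%
  expect_true(all(strong$level %in% c(0.95, 0.99, 0.999, 0.9999, 0.99999)))
  expect_true(all(diff(strong$level) > 0))
})

test_that("basic CI construction agrees with the boot package", {
  skip_if_not_installed("boot")
  set.seed(9)
  a <- rnorm(40, 1); b <- rnorm(40)
  cfg <- gm_config(bootstrap_iterations = 5000, rng_seed = 10)
  ours <- bootstrap_mean_diff_ci(a, b, cfg)[1, ]
  dat <- data.frame(v = c(a, b), g = rep(1:2, each = 40))
  bt <- boot::boot(dat, function(d, i) {
    di <- d[i, ]; mean(di$v[di$g == 1]) - mean(di$v[di$g == 2])
  }, R = 5000, strata = dat$g)
  ci <- boot::boot.ci(bt, type = "basic", conf = 0.95)$basic[4:5]
  expect_equal(unname(c(ours$low, ours$high)), ci, tolerance = 0.08)
})

test_that("bootstrap CI coverage is near nominal on Gaussian differences", {
  cfg <- gm_config(bootstrap_iterations = 999, rng_seed = 1)
  set.seed(42)
  n_rep <- 500
  covered <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(20); b <- rnorm(20)
    ci <- bootstrap_mean_diff_ci(a, b,
                                 gm_config(bootstrap_iterations = 999,
                                           rng_seed = i))[1, ]
    ci$low <= 0 && ci$high >= 0
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("unbiased Cohen's d applies the small-sample correction", {
  d <- cohens_d_unbiased(c(1, 2, 3), c(2, 3, 4))
  expect_equal(d$d_uncorrected, -1)
  expect_equal(d$d, -0.8)
  expect_equal(d$band, "large")
  expect_equal(cohens_d_unbiased(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d_unbiased(c(2, 3, 4), c(1, 2, 3))$d, 0.8)
  expect_error(cohens_d_unbiased(rep(1, 3), rep(1, 3)), "pooled")
})

test_that("rank-biserial correlation spans [-1, 1]", {
  expect_equal(rank_biserial_wilcoxon(c(1, 2, 3))$r_rb, 1)
  expect_equal(rank_biserial_wilcoxon(c(-1, -2, -0.5))$r_rb, -1)
  expect_equal(rank_biserial_wilcoxon(c(1, -1))$r_rb, 0)
  expect_error(rank_biserial_wilcoxon(c(0, 0)), "zero")
})

test_that("Kendall's W matches the variance-of-rank-sums oracle", {
  ident <- matrix(c(1, 2, 3, 10, 20, 30, 5, 6, 7), 3, byrow = TRUE)
  expect_equal(kendalls_w(ident)$W, 1)
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(sample(1:4, 15, replace = TRUE), 5, 3)  # ties likely
    expect_equal(kendalls_w(m)$W, brute_force_w(m), tolerance = 1e-12)
  }
  expect_error(kendalls_w(matrix(1:3, 3, 1)), "2 subjects and 2 conditions")
})

test_that("Friedman chi-squared and W handle two-condition designs", {
  conc <- cbind(c(1, 2, 3), c(4, 5, 6))
  f <- friedman_with_w(conc)
  expect_equal(f$W, 1)
  set.seed(12)
  rnd <- matrix(rnorm(40), 10, 4)
  fr <- friedman_with_w(rnd)
  expect_lt(fr$W, 0.4)
  expect_equal(fr$W, unname(stats::friedman.test(rnd)$statistic) / (10 * 3))
  expect_error(friedman_with_w(cbind(c(1, NA), c(2, 3))), "complete")
})

test_that("Cramer's V composes the chi-squared statistic correctly", {
  expect_equal(cramers_v(matrix(c(10, 20, 10, 20), 2))$V, 0)
  expect_equal(cramers_v(diag(c(7, 9)))$V, 1)
  set.seed(13)
  for (i in 1:10) {
    tab <- matrix(sample(5:30, 9), 3)
    v <- cramers_v(tab)
    expect_equal(v$V, sqrt(brute_force_chisq(tab) / (sum(tab) * 2)),
                 tolerance = 1e-12)
    expect_gte(v$V, 0); expect_lte(v$V, 1)
  }
})

test_that("distribution tests report p and effect size together", {
  same <- matrix(c(20, 30, 20, 30), 2)
  out <- chi_square_distribution_test(same)
  expect_gt(out$p, 0.99)
  expect_equal(out$cramers_v, 0)
  disjoint <- matrix(c(25, 0, 0, 25), 2)
  expect_equal(chi_square_distribution_test(disjoint)$cramers_v, 1)
  # hand-computed 2x2: chi2 = n(ad - bc)^2 / (r1 r2 c1 c2)
  tab <- matrix(c(12, 8, 5, 15), 2)
  hand <- sum(tab) * (12 * 15 - 5 * 8)^2 / (20 * 20 * 17 * 23)
  expect_equal(chi_square_distribution_test(tab)$chi_sq, hand,
               tolerance = 1e-12)
})

test_that("repeated-measures correlation finds the common slope", {
  s <- rep(1:3, each = 4); x <- rep(1:4, 3)
  y <- x + rep(c(0, 5, 9), each = 4)
  r <- suppressWarnings(repeated_measures_correlation(s, x, y))
  expect_equal(r$r_rm, 1)
  expect_equal(r$R2_rm, 1)
  # perfect fits provoke the lm ANOVA reliability warning; harmless here
  yneg <- -x + rep(c(0, 5, 9), each = 4)
  rn <- suppressWarnings(repeated_measures_correlation(s, x, yneg))
  expect_equal(rn$r_rm, -1)
  set.seed(14)
  s2 <- rep(1:6, each = 10); x2 <- rnorm(60)
  y2 <- rnorm(60) + rep(rnorm(6, sd = 3), each = 10)
  r2 <- repeated_measures_correlation(s2, x2, y2)
  expect_lt(abs(r2$r_rm), 0.35)
  expect_warning(repeated_measures_correlation(
    c(1, 1, 2, 3, 3), c(1, 2, 3, 1, 2), c(1, 2.2, 3, 0.9, 2.3)), "dropped")
})

test_that("repeated-measures correlation recovers a planted IC/period slope", {
  set.seed(15)
  subj <- rep(1:8, each = 30)
  ic <- runif(240, 20, 80)
  period <- 0.01 * ic + rep(runif(8, 1, 2), each = 30) + rnorm(240, 0, 0.05)
  r <- repeated_measures_correlation(subj, ic, period)
  expect_gt(r$r_rm, 0.5)
  expect_true(r$band_r %in% c("medium", "large"))
  expect_lt(r$p, 1e-6)
})

test_that("equal-slopes ANCOVA recovers a planted group offset", {
  set.seed(16)
  x <- runif(80, 0.2, 1); g <- rep(c("S", "H"), each = 40)
  delta <- 0.25
  y <- x + delta * (g == "H") + rnorm(80, 0, 0.05)
  a <- ancova_equal_slopes(g, x, y)
  expect_true(a$slopes_homogeneous)
  expect_equal(a$common_slope, 1, tolerance = 0.1)
  pw <- a$pairwise
  d_hat <- abs(pw$difference[1])
  expect_lt(abs(d_hat - delta), 2.5 * pw$se[1])
  expect_lt(pw$p_adjusted[1], 0.001)
  # group on the identity line: null-line test non-significant
  nl <- a$null_line
  expect_gt(nl$p[nl$group == "S"], 0.05)
  expect_lt(nl$p[nl$group == "H"], 0.01)
})

test_that("heterogeneous slopes stop the ANCOVA before adjusted means", {
  set.seed(17)
  x <- runif(60, 0, 1); g <- rep(c("A", "B"), each = 30)
  y <- ifelse(g == "A", 2 * x, -2 * x) + rnorm(60, 0, 0.05)
  a <- ancova_equal_slopes(g, x, y)
  expect_false(a$slopes_homogeneous)
  expect_null(a$adjusted_means)
  expect_null(a$pairwise)
})

test_that("Holm-Sidak adjustment is monotone and bounded", {
  p <- c(0.001, 0.04, 0.03, 0.2, 0.9)
  adj <- gastricmill:::holm_sidak(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  expect_equal(order(adj), order(p))
  expect_equal(gastricmill:::holm_sidak(0.02), 0.02)
})

test_that("effect-size bands honour the printed cutoffs at boundaries", {
  expect_equal(effect_band(0.19, "cohens_d"), "none")
  expect_equal(effect_band(0.2, "cohens_d"), "small")
  expect_equal(effect_band(0.5, "cohens_d"), "medium")
  expect_equal(effect_band(-0.8, "cohens_d"), "large")
  expect_equal(effect_band(0.1, "rank_biserial"), "small")
  expect_equal(effect_band(0.3, "rank_biserial"), "medium")
  expect_equal(effect_band(0.5, "rank_biserial"), "large")
  expect_equal(effect_band(0.19, "kendalls_w"), "small")
  expect_equal(effect_band(0.2, "kendalls_w"), "medium")
  expect_equal(effect_band(0.4, "kendalls_w"), "large")
  expect_equal(effect_band(0.07, "cramers_v"), "small")
  expect_equal(effect_band(0.21, "cramers_v"), "medium")
  expect_equal(effect_band(0.35, "cramers_v"), "large")
  expect_equal(effect_band(1.5, "odds_ratio"), "small")
  expect_equal(effect_band(3.0, "odds_ratio"), "large")
  expect_equal(effect_band(1 / 3, "odds_ratio"), "large")
})
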