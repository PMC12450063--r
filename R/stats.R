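#' Effect-size magnitude band
#'
#' Maps an effect-size value to the conventional small/medium/large band for
#' its metric, using the standard cutoffs: Cohen's d 0.2/0.5/0.8,
#' rank-biserial 0.1/0.3/0.5, Kendall's W 0.2/0.4, Cramer's V 0.07/0.21/0.35,
#' odds ratio 1.5/2/3, repeated-measures r 0.2/0.5/0.8 and R-squared
#' 0.02/0.13/0.26. Banding is sign-independent where the metric is signed.
#'
#' @param value effect-size value.
#' @param kind one of `"cohens_d"`, `"rank_biserial"`, `"kendalls_w"`,
#'   `"cramers_v"`, `"odds_ratio"`, `"r_rm"`, `"R2_rm"`.
#' @return `"none"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_band <- function(value,
                        kind = c("cohens_d", "rank_biserial", "kendalls_w",
                                 "cramers_v", "odds_ratio", "r_rm", "R2_rm")) {
  kind <- match.arg(kind)
  v <- abs(value)
  cuts <- switch(kind,
                 cohens_d = c(0.2, 0.5, 0.8),
                 rank_biserial = c(0.1, 0.3, 0.5),
                 kendalls_w = c(0, 0.2, 0.4),
                 cramers_v = c(0.07, 0.21, 0.35),
                 odds_ratio = c(1.5, 2, 3),
                 r_rm = c(0.2, 0.5, 0.8),
                 R2_rm = c(0.02, 0.13, 0.26))
  if (kind == "odds_ratio" && v < 1) v <- 1 / v
  c("none", "small", "medium", "large")[findInterval(v, cuts) + 1L]
}

#' Odds and odds ratio of gastric mill rhythm occurrence
#'
#' Odds per condition are GMR segments over non-GMR segments (irregular and
#' no-rhythm combined); the odds ratio is `oddsA / oddsB`. The default 95%
#' confidence interval uses the Woolf log-normal method; an optional
#' Haldane-Anscombe continuity correction (+0.5 to every cell) handles zero
#' cells.
#'
#' @param countsA,countsB length-2 vectors `(n_gmr, n_non)`.
#' @param conf_level confidence level for the odds-ratio CI.
#' @param continuity add 0.5 to all cells before computing.
#' @return A list with `odds_a`, `odds_b`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `conf_level`, `band`.
#' @export
#' @examples
#' odds_and_or(c(38, 6), c(42, 22))$odds_ratio  # ~3.32
odds_and_or <- function(countsA, countsB, conf_level = 0.95,
                        continuity = FALSE) {
  stopifnot(length(countsA) == 2L, length(countsB) == 2L,
            all(c(countsA, countsB) >= 0))
  cells <- c(countsA, countsB)
  if (continuity) cells <- cells + 0.5
  if (any(cells[c(2L, 4L)] == 0))
    stop("zero non-GMR count; enable the continuity correction")
  if (any(cells[c(1L, 3L)] == 0))
    stop("zero GMR count; enable the continuity correction")
  odds_a <- cells[1L] / cells[2L]
  odds_b <- cells[3L] / cells[4L]
  or <- odds_a / odds_b
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm((1 + conf_level) / 2)
  list(odds_a = odds_a, odds_b = odds_b, odds_ratio = or,
       ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       conf_level = conf_level, band = effect_band(or, "odds_ratio"))
}

#' Cascading basic-method bootstrap CI on a mean difference
#'
#' Builds a basic (reverse percentile) bootstrap confidence interval on
#' `mean(samplesA) - mean(samplesB)` at 95%; when that interval excludes
#' zero, further intervals are constructed at 99%, 99.9%, 99.99% and 99.999%,
#' stopping at the first level whose interval crosses zero (or at 99.999%).
#' One set of bootstrap resamples is shared across levels.
#'
#' @param samplesA,samplesB numeric vectors (>= 2 values each).
#' @param cfg a [gm_config()]; uses `bootstrap_iterations` and `rng_seed`.
#' @return A data frame with one row per constructed level: `level`, `low`,
#'   `high`, `estimate`, `significant` (interval excludes zero),
#'   `n_iterations`.
#' @export
bootstrap_mean_diff_ci <- function(samplesA, samplesB, cfg = gm_config()) {
  if (length(samplesA) < 2L || length(samplesB) < 2L)
    stop("each sample needs at least 2 values")
  B <- cfg$bootstrap_iterations
  est <- mean(samplesA) - mean(samplesB)
  .with_seed(cfg$rng_seed, {
    mA <- rowMeans(matrix(samplesA[sample.int(length(samplesA),
                                              length(samplesA) * B,
                                              replace = TRUE)], nrow = B))
    mB <- rowMeans(matrix(samplesB[sample.int(length(samplesB),
                                              length(samplesB) * B,
                                              replace = TRUE)], nrow = B))
    d <- mA - mB
    levels <- c(0.95, 0.99, 0.999, 0.9999, 0.99999)
    rows <- list()
    for (lv in levels) {
      q <- stats::quantile(d, c((1 - lv) / 2, (1 + lv) / 2), names = FALSE)
      low <- 2 * est - q[2L]; high <- 2 * est - q[1L]
      sig <- low > 0 || high < 0
      rows[[length(rows) + 1L]] <- data.frame(
        level = lv, low = low, high = high, estimate = est,
        significant = sig, n_iterations = B)
      if (!sig) break
    }
    do.call(rbind, rows)
  })
}

#' Unbiased (Hedges-corrected) Cohen's d
#'
#' Standardized mean difference `(mean(A) - mean(B)) / s_pooled` with the
#' small-sample correction `J = 1 - 3 / (4 df - 1)`, `df = nA + nB - 2`.
#' Bands at 0.2 / 0.5 / 0.8.
#'
#' @param samplesA,samplesB numeric vectors.
#' @return A list with `d` (corrected), `d_uncorrected`, `band`.
#' @export
#' @examples
#' cohens_d_unbiased(c(1, 2, 3), c(2, 3, 4))$d  # -0.8
cohens_d_unbiased <- function(samplesA, samplesB) {
  nA <- length(samplesA); nB <- length(samplesB)
  stopifnot(nA >= 2L, nB >= 2L)
  df <- nA + nB - 2L
  sp2 <- ((nA - 1) * stats::var(samplesA) + (nB - 1) * stats::var(samplesB)) /
    df
  if (sp2 <= 0) stop("zero pooled standard deviation")
  d0 <- (mean(samplesA) - mean(samplesB)) / sqrt(sp2)
  j <- 1 - 3 / (4 * df - 1)
  list(d = j * d0, d_uncorrected = d0, band = effect_band(j * d0, "cohens_d"))
}

#' Rank-biserial correlation for paired differences
#'
#' Effect size of the Wilcoxon signed-rank test: the signed ranks of the
#' nonzero paired differences are split into positive and negative sums and
#' the statistic is their difference over the total rank sum, in `[-1, 1]`.
#' `1` means every difference is positive.
#'
#' @param paired_diffs numeric vector of paired differences.
#' @return A list with `r_rb` and `band` (cutoffs 0.1 / 0.3 / 0.5).
#' @export
rank_biserial_wilcoxon <- function(paired_diffs) {
  d <- paired_diffs[paired_diffs != 0]
  if (!length(d)) stop("all paired differences are zero")
  r <- rank(abs(d))
  pos <- sum(r[d > 0]); neg <- sum(r[d < 0])
  r_rb <- (pos - neg) / (pos + neg)
  list(r_rb = r_rb, band = effect_band(r_rb, "rank_biserial"))
}

#' Kendall's coefficient of concordance
#'
#' Tie-corrected Kendall's W over a subjects-by-conditions value matrix:
#' conditions are ranked within each subject (midranks for ties) and
#' `W = (12 S - 3 n^2 k (k+1)^2) / (n^2 k (k^2 - 1) - n T)` where `S` is the
#' sum of squared rank sums and `T` the tie correction. Bands: small < 0.2,
#' medium 0.2-0.39, large >= 0.4.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns.
#' @return A list with `W` and `band`.
#' @export
kendalls_w <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  ranks <- t(apply(values, 1L, rank))
  S <- sum(colSums(ranks)^2)
  Tcorr <- sum(apply(ranks, 1L, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  W <- (12 * S - 3 * n^2 * k * (k + 1)^2) / (n^2 * k * (k^2 - 1) - n * Tcorr)
  list(W = W, band = effect_band(W, "kendalls_w"))
}

#' Cramer's V of a contingency table
#'
#' `sqrt(chi^2 / (n (min(r, c) - 1)))` from the uncorrected Pearson
#' chi-squared statistic; 0 is complete independence, 1 complete dependence.
#' Bands 0.07 / 0.21 / 0.35.
#'
#' @param table matrix of nonnegative counts, at least 2x2.
#' @return A list with `V`, `chi_sq`, `band`.
#' @export
cramers_v <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L || sum(table) == 0)
    stop("need a nonempty table of at least 2x2")
  chi <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  v <- sqrt(unname(chi$statistic) /
              (sum(table) * (min(dim(table)) - 1L)))
  list(V = v, chi_sq = unname(chi$statistic),
       band = effect_band(v, "cramers_v"))
}

#' Chi-squared test on a category-by-condition distribution
#'
#' Pearson chi-squared test of homogeneity with Cramer's V as effect size.
#'
#' @param table counts matrix (categories by conditions), at least 2x2.
#' @return A list with `chi_sq`, `df`, `p`, `cramers_v`, `band`.
#' @export
chi_square_distribution_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2x2 table")
  ch <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ch$expected == 0))
    stop("zero expected count; test undefined for this table")
  v <- cramers_v(table)
  list(chi_sq = unname(ch$statistic), df = unname(ch$parameter),
       p = ch$p.value, cramers_v = v$V, band = v$band)
}

#' Friedman test with Kendall's W
#'
#' Friedman chi-squared on a complete subjects-by-conditions block design
#' (midranks for ties), with `W = chi^2_F / (n (k - 1))` as the concordance
#' effect size. Two-condition designs are permitted.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns; no
#'   missing cells.
#' @return A list with `chi_sq`, `df`, `p`, `W`, `band`.
#' @export
friedman_with_w <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing cells; Friedman needs complete blocks")
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  ft <- stats::friedman.test(values)
  W <- unname(ft$statistic) / (n * (k - 1L))
  list(chi_sq = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value, W = W, band = effect_band(W, "kendalls_w"))
}

#' Repeated-measures correlation
#'
#' Common within-subject association between x and y: a linear model of y on
#' x with subject intercepts removes between-subject variation, and the
#' correlation is `sign(slope) * sqrt(SS_x / (SS_x + SS_error))` from the
#' sequential ANOVA with subject fitted first. Subjects with fewer than 2
#' points are dropped with a warning.
#'
#' @param subject subject identifiers.
#' @param x,y numeric measurements.
#' @param conf_level level for the Fisher-z confidence interval.
#' @return A list with `r_rm`, `R2_rm`, `ci_low`, `ci_high`, `p`, `df`,
#'   `slope`, `band_r`, `band_R2`, `n_subjects`.
#' @export
repeated_measures_correlation <- function(subject, x, y, conf_level = 0.95) {
  stopifnot(length(subject) == length(x), length(x) == length(y))
  keep <- stats::complete.cases(subject, x, y)
  subject <- subject[keep]; x <- x[keep]; y <- y[keep]
  counts <- table(subject)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning(sprintf("%d subject(s) with < 2 points dropped", length(small)))
    keep <- !(subject %in% small)
    subject <- subject[keep]; x <- x[keep]; y <- y[keep]
  }
  if (length(unique(subject)) < 2L)
    stop("need at least 2 subjects with at least 2 points each")
  f <- factor(subject)
  m <- stats::lm(y ~ f + x)
  a <- stats::anova(m)
  ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
  df_e <- a["Residuals", "Df"]
  slope <- unname(stats::coef(m)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  p <- a["x", "Pr(>F)"]
  zcrit <- stats::qnorm((1 + conf_level) / 2)
  se_z <- 1 / sqrt(max(df_e - 1L, 1L))
  ci <- tanh(atanh(min(max(r, -1 + 1e-12), 1 - 1e-12)) + c(-1, 1) *
               zcrit * se_z)
  list(r_rm = r, R2_rm = r^2, ci_low = ci[1L], ci_high = ci[2L], p = p,
       df = df_e, slope = slope, band_r = effect_band(r, "r_rm"),
       band_R2 = effect_band(r^2, "R2_rm"),
       n_subjects = length(unique(subject)))
}

# Step-down Holm-Sidak adjustment: p_(i) -> 1 - (1 - p_(i))^(m - i + 1),
# enforced monotone.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1L)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Equal-slopes ANCOVA with Holm-Sidak pairwise comparisons
#'
#' Tests the group-by-covariate interaction; when slopes are homogeneous
#' (interaction p above `alpha`), fits the common-slope model, reports
#' covariate-adjusted group means at the grand-mean covariate value, all
#' pairwise adjusted-mean differences with Holm-Sidak correction, and a
#' per-group test of the fitted prediction line against the identity line
#' (slope 1, intercept 0; no incubation effect) via an independent-samples t
#' test of predictions against baselines.
#'
#' @param group group labels.
#' @param x baseline covariate values.
#' @param y response values.
#' @param alpha significance level for the interaction test.
#' @return A list with `interaction_p`, `slopes_homogeneous`, `common_slope`,
#'   `adjusted_means` (data frame), `pairwise` (data frame with raw and
#'   Holm-Sidak adjusted p), `null_line` (per-group t test of predictions vs
#'   identity). `common_slope`, `adjusted_means` and `pairwise` are `NULL`
#'   when slopes are heterogeneous.
#' @export
ancova_equal_slopes <- function(group, x, y, alpha = 0.05) {
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 3L)) stop("need at least 3 points per group")
  if (stats::var(x) == 0) stop("degenerate covariate (no variance)")
  full <- stats::lm(y ~ x * g)
  reduced <- stats::lm(y ~ x + g)
  inter <- stats::anova(reduced, full)
  p_int <- inter[2L, "Pr(>F)"]
  out <- list(interaction_p = p_int, slopes_homogeneous = p_int > alpha,
              common_slope = NULL, adjusted_means = NULL, pairwise = NULL,
              null_line = NULL)
  if (!out$slopes_homogeneous) return(out)
  m <- reduced
  slope <- unname(stats::coef(m)["x"])
  xbar <- mean(x)
  lv <- levels(g)
  nd <- data.frame(x = xbar, g = factor(lv, levels = lv))
  pr <- stats::predict(m, newdata = nd, se.fit = TRUE)
  out$common_slope <- slope
  out$adjusted_means <- data.frame(group = lv, adjusted_mean = unname(pr$fit),
                                   se = unname(pr$se.fit))
  pairs <- utils::combn(lv, 2L)
  V <- stats::vcov(m)
  sigma2 <- summary(m)$sigma^2
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    # contrast on the group coefficients (treatment coding)
    cvec <- stats::setNames(rep(0, length(stats::coef(m))),
                            names(stats::coef(m)))
    if (a != lv[1L]) cvec[paste0("g", a)] <- 1
    if (b != lv[1L]) cvec[paste0("g", b)] <- -1
    diff <- sum(cvec * stats::coef(m))
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tstat <- diff / se
    p <- 2 * stats::pt(-abs(tstat), df = m$df.residual)
    data.frame(group_a = a, group_b = b, difference = diff, se = se,
               t = tstat, p_raw = p)
  })
  pw <- do.call(rbind, rows)
  pw$p_adjusted <- holm_sidak(pw$p_raw)
  out$pairwise <- pw
  out$null_line <- do.call(rbind, lapply(lv, function(lev) {
    idx <- g == lev
    pred <- stats::predict(m, newdata = data.frame(
      x = x[idx], g = factor(lev, levels = lv)))
    tt <- stats::t.test(pred, x[idx])
    data.frame(group = lev, t = unname(tt$statistic), p = tt$p.value,
               mean_predicted = mean(pred), mean_baseline = mean(x[idx]))
  }))
  out
}
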