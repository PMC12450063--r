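# Shared fixture builders and independent oracles.

make_train <- function(times, neuron = "IC", pad = 1) {
  lo <- if (length(times)) min(times) - pad else 0
  hi <- if (length(times)) max(times) + pad else pad
  spike_train(neuron, times, lo, hi)
}

# Brute-force burst splitter: examine every gap explicitly.
brute_force_bursts <- function(times, ceiling) {
  if (!length(times)) return(list())
  groups <- list(times[1])
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] > ceiling)
      groups[[length(groups) + 1]] <- numeric(0)
    groups[[length(groups)]] <- c(groups[[length(groups)]], times[i])
  }
  Filter(function(g) length(g) >= 2, groups)
}

# Brute-force linear-interpolation quantile (type 7 definition from first
# principles): h = (n - 1) p + 1, interpolate between floor(h) and ceiling(h).
brute_force_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# Brute-force Kendall's W via the variance-of-rank-sums formula with midranks.
brute_force_w <- function(values) {
  ranks <- t(apply(values, 1, rank))
  n <- nrow(values); k <- ncol(values)
  Rj <- colSums(ranks)
  S <- sum((Rj - mean(Rj))^2)
  Tcorr <- sum(apply(ranks, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  }))
  12 * S / (n^2 * (k^3 - k) - n * Tcorr)
}

# Hand-rolled Pearson chi-squared statistic.
brute_force_chisq <- function(tab) {
  exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_)^2 / exp_)
}

# Random spike train with mixed short/long gaps for oracle comparisons.
random_train <- function(n = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gaps <- sample(c(stats::runif(n, 0.01, 0.3), stats::runif(n, 0.5, 5)), n)
  cumsum(gaps)
}
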