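#' Bin one cycle's spikes by phase
#'
#' Sorts a cycle's spikes into `n_bins` phase bins: a spike at phase
#' `phi` in `[0, 1)` of the cycle lands in bin `floor(n_bins * phi)`
#' (0-indexed; bin 0 opens at the IC burst onset). Counts sum to the number
#' of in-cycle spikes.
#'
#' @param times spike times (numeric or [spike_train()]).
#' @param cycle a list/one-row data frame with `onset` and `period`.
#' @param n_bins number of bins (default 100).
#' @return Integer vector of `n_bins` counts.
#' @export
#' @examples
#' bin_cycle(c(0, 2.5), list(onset = 0, period = 10))[c(1, 26)]
bin_cycle <- function(times, cycle, n_bins = 100L) {
  if (inherits(times, "spike_train")) times <- times$times
  stopifnot(cycle$period > 0)
  ph <- (times - cycle$onset) / cycle$period
  ph <- ph[ph >= 0 & ph < 1]
  tabulate(pmin(floor(n_bins * ph), n_bins - 1L) + 1L, nbins = n_bins)
}

# Segment-level normalized phase profile for one neuron: mean spike count per
# bin across the segment's cycles, divided by the mean bin duration
# (mean cycle period / n_bins), giving approximately firing rate across the
# cycle.
.segment_phase_profile <- function(times, cycles, window, n_bins) {
  in_win <- cycles$onset >= window$start & cycles$onset < window$stop
  if (!any(in_win)) return(NULL)
  cyc <- cycles[in_win, , drop = FALSE]
  counts <- sapply(seq_len(nrow(cyc)), function(i)
    bin_cycle(times, cyc[i, ], n_bins))
  mean_counts <- rowMeans(matrix(counts, nrow = n_bins))
  bin_dur <- mean(cyc$period) / n_bins
  mean_counts / bin_dur
}

#' Per-experiment phase profiles
#'
#' For one recording: per neuron, the 100-bin normalized phase profile of each
#' gastric-mill-rhythm segment, averaged across the experiment's GMR
#' segments. Segments are limited to those classified as gastric mill rhythms
#' (by the supplied labels, or the rule-based classifier when `labels` is
#' `NULL`).
#'
#' @param rec a [gm_recording()].
#' @param cfg a [gm_config()].
#' @param labels optional character vector of per-segment categories (one per
#'   window of [segment_windows()]).
#' @return A neurons-by-bins matrix (rows named by neuron), or `NULL` when the
#'   experiment has no GMR segment.
#' @export
experiment_phase_profile <- function(rec, cfg = gm_config(), labels = NULL) {
  an <- analyze_recording(rec, cfg)
  cycles <- an$gastric$cycles
  if (is.null(cycles) || !nrow(cycles)) return(NULL)
  wins <- suppressWarnings(segment_windows(rec))
  if (is.null(labels))
    labels <- vapply(seq_len(nrow(wins)), function(i)
      rule_based_category(rec, wins[i, ], cfg, an), character(1))
  gmr <- which(labels == "GMR")
  if (!length(gmr)) return(NULL)
  neurons <- names(rec$trains)
  prof <- matrix(NA_real_, length(neurons), cfg$phase_bins,
                 dimnames = list(neurons, NULL))
  for (nm in neurons) {
    seg_profiles <- lapply(gmr, function(i)
      .segment_phase_profile(rec$trains[[nm]]$times, cycles, wins[i, ],
                             cfg$phase_bins))
    seg_profiles <- Filter(Negate(is.null), seg_profiles)
    if (length(seg_profiles))
      prof[nm, ] <- colMeans(do.call(rbind, seg_profiles))
  }
  prof
}

#' Condition-level phase profiles
#'
#' Averages the per-experiment profiles of a condition and reports the
#' across-experiment mean and standard error per bin and neuron.
#'
#' @param recs list of [gm_recording()] objects belonging to one condition.
#' @param cfg a [gm_config()].
#' @param labels optional list of per-recording segment-category vectors.
#' @param condition condition label for the output.
#' @return A list with `table` (data frame: condition, neuron, bin, mean, se,
#'   n) and `per_experiment` (named list: neuron -> experiments-by-bins
#'   matrix).
#' @export
profile_condition <- function(recs, cfg = gm_config(), labels = NULL,
                              condition = "condition") {
  profs <- lapply(seq_along(recs), function(i)
    experiment_phase_profile(recs[[i]], cfg,
                             if (is.null(labels)) NULL else labels[[i]]))
  profs <- Filter(Negate(is.null), profs)
  if (!length(profs))
    stop(sprintf("condition '%s' has no gastric-mill-rhythm segments",
                 condition))
  neurons <- rownames(profs[[1L]])
  per_exp <- lapply(neurons, function(nm)
    do.call(rbind, lapply(profs, function(p) p[nm, ])))
  names(per_exp) <- neurons
  tab <- do.call(rbind, lapply(neurons, function(nm) {
    m <- per_exp[[nm]]
    ok <- stats::complete.cases(m)
    m <- m[ok, , drop = FALSE]
    n <- nrow(m)
    data.frame(condition = condition, neuron = nm,
               bin = seq_len(cfg$phase_bins) - 1L,
               mean = if (n) colMeans(m) else NA_real_,
               se = if (n >= 2L) apply(m, 2L, stats::sd) / sqrt(n) else
                 NA_real_,
               n = n)
  }))
  rownames(tab) <- NULL
  list(table = tab, per_experiment = per_exp)
}

# Basic (reverse percentile) bootstrap CI on mean(xA) - mean(xB).
.basic_boot_ci <- function(xA, xB, B, level) {
  est <- mean(xA) - mean(xB)
  mA <- rowMeans(matrix(xA[sample.int(length(xA), length(xA) * B,
                                      replace = TRUE)], nrow = B))
  mB <- rowMeans(matrix(xB[sample.int(length(xB), length(xB) * B,
                                      replace = TRUE)], nrow = B))
  d <- mA - mB
  q <- stats::quantile(d, c((1 - level) / 2, (1 + level) / 2), names = FALSE,
                       type = 7)
  c(low = 2 * est - q[2L], high = 2 * est - q[1L], estimate = est)
}

#' Cross-condition per-bin phase comparison
#'
#' The bespoke significance heuristic for phase profiles: for each bin and
#' each condition, a basic-method bootstrap confidence interval (level
#' `1 - alpha_phase`, default 99%) is built on the difference of
#' across-experiment group means against each of the other conditions. A bin
#' is flagged for a condition only when both intervals exclude zero, and
#' flags are reported only in runs of at least `min_consecutive_bins`
#' (default 2) consecutive bins. No further multiplicity correction is
#' applied.
#'
#' @param per_experiment named list of three conditions, each an
#'   experiments-by-bins matrix of per-experiment bin values for one neuron.
#' @param cfg a [gm_config()]; uses `alpha_phase`, `min_consecutive_bins`,
#'   `bootstrap_iterations`, `rng_seed`.
#' @return Data frame with columns `condition`, `bin` (0-indexed),
#'   `run_id`; one row per significant bin, zero rows when nothing survives
#'   the heuristic.
#' @export
compare_phase_conditions <- function(per_experiment, cfg = gm_config()) {
  stopifnot(length(per_experiment) == 3L, !is.null(names(per_experiment)))
  conds <- names(per_experiment)
  for (m in per_experiment)
    if (nrow(m) < 2L) stop("need at least 2 experiments per condition")
  n_bins <- ncol(per_experiment[[1L]])
  level <- 1 - cfg$alpha_phase
  B <- cfg$bootstrap_iterations
  .with_seed(cfg$rng_seed, {
    flags <- matrix(FALSE, length(conds), n_bins,
                    dimnames = list(conds, NULL))
    for (ci in seq_along(conds)) {
      others <- setdiff(seq_along(conds), ci)
      for (b in seq_len(n_bins)) {
        ok <- TRUE
        for (oi in others) {
          civ <- .basic_boot_ci(per_experiment[[ci]][, b],
                                per_experiment[[oi]][, b], B, level)
          if (civ["low"] <= 0 && civ["high"] >= 0) { ok <- FALSE; break }
        }
        flags[ci, b] <- ok
      }
    }
    out <- list()
    for (ci in seq_along(conds)) {
      r <- rle(flags[ci, ])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      run_id <- 0L
      for (j in seq_along(r$values)) {
        if (r$values[j] && r$lengths[j] >= cfg$min_consecutive_bins) {
          run_id <- run_id + 1L
          out[[length(out) + 1L]] <- data.frame(
            condition = conds[ci], bin = seq(starts[j], ends[j]) - 1L,
            run_id = sprintf("%s_run%d", conds[ci], run_id))
        }
      }
    }
    if (!length(out))
      return(data.frame(condition = character(), bin = integer(),
                        run_id = character()))
    do.call(rbind, out)
  })
}

#' IC duty cycle of a condition
#'
#' Mean over experiments of the long-IC-burst duty cycle (burst duration over
#' cycle period, percent) across each experiment's gastric-mill-rhythm
#' segments.
#'
#' @param recs list of [gm_recording()] for one condition.
#' @param cfg a [gm_config()].
#' @param labels optional list of per-recording segment category vectors.
#' @return A list with `mean_pct`, `se_pct`, `n` (experiments contributing).
#' @export
duty_cycle_summary <- function(recs, cfg = gm_config(), labels = NULL) {
  per_exp <- c()
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    an <- analyze_recording(rec, cfg)
    cycles <- an$gastric$cycles
    if (is.null(cycles) || !nrow(cycles)) next
    wins <- suppressWarnings(segment_windows(rec))
    lab <- if (is.null(labels)) vapply(seq_len(nrow(wins)), function(k)
      rule_based_category(rec, wins[k, ], cfg, an), character(1))
    else labels[[i]]
    seg_means <- c()
    for (k in which(lab == "GMR")) {
      w <- wins[k, ]
      in_win <- cycles$onset >= w$start & cycles$onset < w$stop
      if (!any(in_win)) next
      seg_means <- c(seg_means,
                     mean(duty_cycle(cycles$ic_burst_duration[in_win],
                                     cycles$period[in_win])))
    }
    if (length(seg_means)) per_exp <- c(per_exp, mean(seg_means))
  }
  if (!length(per_exp)) stop("no gastric-mill-rhythm segments in condition")
  list(mean_pct = mean(per_exp),
       se_pct = if (length(per_exp) >= 2L)
         stats::sd(per_exp) / sqrt(length(per_exp)) else NA_real_,
       n = length(per_exp))
}
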