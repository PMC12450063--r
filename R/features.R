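#' Burstiness of an ISI distribution
#'
#' Sorts the interspike intervals ascending, finds the pair of consecutive
#' sorted ISIs with the largest difference, and returns that difference
#' divided by the larger member of the pair. Values lie in `[0, 1]`: near 0
#' for homogeneous (tonic or perfectly regular) ISIs, near 1 when a clear gap
#' separates short intraburst from long interburst intervals.
#'
#' @param isis numeric vector of ISIs (>= 2 values).
#' @return Burstiness in `[0, 1]`, or `NA` for fewer than 2 ISIs.
#' @export
#' @examples
#' burstiness(c(0.1, 0.1, 0.2, 1.8))  # 1.6 / 1.8
burstiness <- function(isis) {
  if (length(isis) < 2L) return(NA_real_)
  s <- sort(isis)
  d <- diff(s)
  i <- which.max(d)
  if (d[i] == 0) return(0)
  d[i] / s[i + 1L]
}

#' Second-order to first-order ISI ratio
#'
#' The mean absolute second-order difference of the spike times divided by the
#' mean first-order ISI. Zero for perfectly regular spiking; grows with
#' cycle-to-cycle irregularity.
#'
#' @param times numeric vector of sorted spike times (>= 3 values).
#' @return The ratio, or `NA` for fewer than 3 spikes.
#' @export
#' @examples
#' isi_order_ratio(c(0, 1, 3))  # 1 / 1.5
isi_order_ratio <- function(times) {
  if (length(times) < 3L) return(NA_real_)
  isi <- diff(times)
  mean(abs(diff(isi))) / mean(isi)
}

#' Largest to second-largest ISI ratio
#'
#' @param isis numeric vector of ISIs (>= 2 values).
#' @return `max / second max`, always >= 1; `NA` for fewer than 2 ISIs.
#' @export
max_isi_ratio <- function(isis) {
  if (length(isis) < 2L) return(NA_real_)
  s <- sort(isis, decreasing = TRUE)
  if (s[2L] == 0) return(Inf)
  s[1L] / s[2L]
}

#' Deciles of a sample
#'
#' Ten summary quantiles at p = 0.1, 0.2, ..., 1.0 with linear interpolation,
#' used to reduce variable-length ISI and phase vectors to a fixed length.
#'
#' @param values numeric vector.
#' @return Numeric vector of 10 non-decreasing values; all `NA` when empty.
#' @export
deciles <- function(values) {
  if (!length(values)) return(rep(NA_real_, 10L))
  unname(stats::quantile(values, probs = seq(0.1, 1, by = 0.1), type = 7,
                         names = FALSE))
}

#' Phase of spikes within gastric cycles
#'
#' For each spike falling inside a gastric cycle, returns
#' `(t - onset) / period`, in `[0, 1)`, relative to the cycle-defining long IC
#' burst onsets (phase 0 is IC burst onset). Spikes outside all cycles are
#' dropped.
#'
#' @param times numeric spike times (or a [spike_train()]).
#' @param cycles gastric cycle data frame with `onset` and `period`.
#' @return Numeric vector of phases in `[0, 1)`.
#' @export
phase_of_spikes <- function(times, cycles) {
  if (inherits(times, "spike_train")) times <- times$times
  if (is.null(cycles) || !nrow(cycles)) {
    warning("no gastric cycles; no phases computed")
    return(numeric(0))
  }
  on <- cycles$onset
  idx <- findInterval(times, on)
  ok <- idx >= 1L & idx <= nrow(cycles)
  ph <- rep(NA_real_, length(times))
  ph[ok] <- (times[ok] - on[idx[ok]]) / cycles$period[idx[ok]]
  ph <- ph[ok & ph < 1]
  ph
}

# Neurons entering the segment feature vector, in block order.
FEATURE_NEURONS <- c("IC", "PD", "LG", "DG", "AM")

#' Feature vector for one 200-s segment
#'
#' Builds the fixed-length (120) descriptor of a segment: for each of the
#' neurons IC, PD, LG, DG and AM, the 10 ISI deciles, the 10 phase deciles
#' (phase relative to the gastric-mill-timed IC bursting, after prepeak
#' removal), the mean intraburst firing rate, the second-to-first-order ISI
#' ratio, the largest-to-second-largest ISI ratio, and the burstiness metric.
#' Undefined entries (absent neuron, too few spikes, no gastric cycles) are
#' `NA` sentinels; [fit_cluster_model()] imputes them at the dataset mean.
#'
#' @param rec a [gm_recording()].
#' @param window a one-row window from [segment_windows()].
#' @param cfg a [gm_config()].
#' @param analysis optional precomputed [analyze_recording()] result for `rec`
#'   (avoids recomputation across the four segments).
#' @return Named numeric vector of length 120.
#' @export
featurize_segment <- function(rec, window, cfg = gm_config(),
                              analysis = NULL) {
  if (is.null(analysis)) analysis <- analyze_recording(rec, cfg)
  cycles <- analysis$gastric$cycles
  blocks <- lapply(FEATURE_NEURONS, function(nm) {
    tr <- rec$trains[[nm]]
    if (is.null(tr))
      return(rep(NA_real_, 24L))
    seg <- slice_train(tr, window)
    isis <- diff(seg$times)
    ph <- if (is.null(cycles) || !nrow(cycles)) numeric(0) else
      suppressWarnings(phase_of_spikes(seg$times, cycles))
    b <- analysis$bursts[[nm]]
    if (nm == "IC") b <- analysis$ic_gastric_bursts
    bw <- if (is.null(b) || !nrow(b))
      NULL else bursts_in_window(b, window)
    rate <- if (is.null(bw) || !nrow(bw)) NA_real_ else mean(bw$rate_hz)
    c(deciles(isis),
      if (length(ph)) deciles(ph) else rep(NA_real_, 10L),
      rate,
      isi_order_ratio(seg$times),
      max_isi_ratio(isis),
      burstiness(isis))
  })
  v <- unlist(blocks)
  names(v) <- as.vector(vapply(FEATURE_NEURONS, function(nm)
    c(paste0(nm, "_isi_d", 1:10), paste0(nm, "_phase_d", 1:10),
      paste0(nm, "_rate"), paste0(nm, "_isi2_1"), paste0(nm, "_max_ratio"),
      paste0(nm, "_burstiness")), character(24L)))
  v
}

#' Featurize every segment of a batch of recordings
#'
#' Runs [analyze_recording()] once per recording, then [featurize_segment()]
#' for each of its segment windows, and collects the auxiliary per-segment
#' rhythm statistics needed for cluster-to-category mapping and rule-based
#' classification.
#'
#' @param recs list of [gm_recording()] objects.
#' @param cfg a [gm_config()].
#' @return A list with `features` (matrix, one row per segment), `info` (data
#'   frame: subject, condition, segment index, long-IC-burst count, gastric
#'   cycle count, mean period, period CV, interrupted-cycle count, rule-based
#'   category).
#' @export
featurize_batch <- function(recs, cfg = gm_config()) {
  rows <- list(); info <- list()
  for (rec in recs) {
    an <- analyze_recording(rec, cfg)
    wins <- suppressWarnings(segment_windows(rec))
    for (i in seq_len(nrow(wins))) {
      w <- wins[i, ]
      rows[[length(rows) + 1L]] <- featurize_segment(rec, w, cfg, an)
      info[[length(info) + 1L]] <- cbind(
        data.frame(subject = rec$subject_id, condition = rec$condition,
                   segment = w$index),
        segment_rhythm_stats(an, w, cfg))
    }
  }
  list(features = do.call(rbind, rows), info = do.call(rbind, info))
}

# Per-segment rhythm bookkeeping: long bursts, cycles, periods, interruptions,
# coordination, and the rule-based category.
segment_rhythm_stats <- function(analysis, window, cfg = gm_config()) {
  long <- analysis$long_ic
  n_long <- if (is.null(long)) 0L else nrow(bursts_in_window(long, window))
  cyc <- analysis$gastric$cycles
  members <- analysis$gastric$members
  in_win <- if (is.null(cyc) || !nrow(cyc)) logical(0) else
    cyc$onset >= window$start & cyc$onset < window$stop
  periods <- if (any(in_win)) cyc$period[in_win] else numeric(0)
  n_cycles <- length(periods)
  coordinated <- FALSE
  if (n_cycles >= 1L && !is.null(members) && nrow(members)) {
    idx <- which(in_win)
    coordinated <- all(vapply(idx, function(ci) {
      m <- members$neuron[!is.na(members$cycle) & members$cycle == ci]
      all(c("LG", "DG", "AM") %in% m)
    }, logical(1)))
  }
  py <- analysis$pyloric
  n_int <- if (is.null(py)) 0L else
    sum(py$is_interrupted & py$onset >= window$start & py$onset < window$stop)
  mean_period <- if (n_cycles) mean(periods) else NA_real_
  cv <- if (n_cycles >= 2L) stats::sd(periods) / mean(periods) else NA_real_
  category <- if (n_long == 0L) "NONE"
  else if (n_cycles >= 3L && !is.na(mean_period) && mean_period < 40 &&
           coordinated && n_int >= n_cycles) "GMR"
  else "IRREGULAR"
  data.frame(n_long_ic_bursts = n_long, n_cycles = n_cycles,
             mean_period_s = mean_period, period_cv = cv,
             n_interruptions = n_int, coordinated = coordinated,
             rule_category = category)
}

#' Rule-based rhythm category of one segment
#'
#' The interpretable classifier used to validate the cluster-to-category
#' mapping: a segment is a gastric mill rhythm (GMR) when it holds at least 3
#' gastric cycles with mean period below 40 s, every cycle contains at least
#' one LG, DG and AM burst, and interrupted pyloric cycles occur at least once
#' per gastric cycle on average; NONE when it has no long IC bursts;
#' IRREGULAR otherwise.
#'
#' @param rec a [gm_recording()].
#' @param window one-row window from [segment_windows()].
#' @param cfg a [gm_config()].
#' @param analysis optional precomputed [analyze_recording()] result.
#' @return One of `"GMR"`, `"IRREGULAR"`, `"NONE"`.
#' @export
rule_based_category <- function(rec, window, cfg = gm_config(),
                                analysis = NULL) {
  if (is.null(analysis)) analysis <- analyze_recording(rec, cfg)
  segment_rhythm_stats(analysis, window, cfg)$rule_category
}

#' Transitions and persistence across consecutive segments
#'
#' Counts category transitions between consecutive segments of each
#' incubation, flags incubations where a category persisted through all
#' segments, and flags "non-adjacent" transitions (direct GMR <-> NONE jumps,
#' which skip the intermediate irregular state).
#'
#' @param labels a character vector of one incubation's ordered segment
#'   categories, or a list of such vectors (one per incubation).
#' @return A list with `counts` (3x3 from-by-to matrix), `persistence`
#'   (logical per incubation: a single category across all segments),
#'   `n_nonadjacent` (count of GMR <-> NONE transitions).
#' @export
transition_table <- function(labels) {
  if (!is.list(labels)) labels <- list(labels)
  cats <- c("GMR", "IRREGULAR", "NONE")
  counts <- matrix(0L, 3L, 3L, dimnames = list(from = cats, to = cats))
  persistence <- logical(length(labels))
  n_nonadj <- 0L
  for (i in seq_along(labels)) {
    lab <- labels[[i]]
    stopifnot(all(lab %in% cats))
    persistence[i] <- length(unique(lab)) == 1L
    if (length(lab) >= 2L) {
      for (k in seq_len(length(lab) - 1L)) {
        counts[lab[k], lab[k + 1L]] <- counts[lab[k], lab[k + 1L]] + 1L
        if (sort(c(lab[k], lab[k + 1L]))[1L] == "GMR" &&
            sort(c(lab[k], lab[k + 1L]))[2L] == "NONE")
          n_nonadj <- n_nonadj + 1L
      }
    }
  }
  list(counts = counts, persistence = persistence, n_nonadjacent = n_nonadj)
}
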