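#' Extract long gastric-mill-timed IC bursts
#'
#' Long IC bursts (duration at least `cfg$long_ic_burst_min_s`, default 1 s,
#' inclusive) define the gastric mill cycle. Input bursts should come from
#' [detect_bursts()] with the slow (2 s) ceiling.
#'
#' @param ic_bursts burst data frame for the IC neuron.
#' @param cfg a [gm_config()].
#' @return The subset of long bursts.
#' @export
long_ic_bursts <- function(ic_bursts, cfg = gm_config()) {
  out <- ic_bursts[ic_bursts$duration >= cfg$long_ic_burst_min_s, ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify prepeak IC bursts
#'
#' A brief gastric-mill-timed IC burst (duration 1-2 s) followed within 5 s by
#' a longer (> 2 s) burst is a "prepeak": it is treated as part of the
#' preceding cycle and excluded from cycle-period determination, but retained
#' for burst-count, duration and rate statistics.
#'
#' @param long_bursts time-ordered long IC burst data frame.
#' @return A list with `cycle_defining` (bursts whose onsets delimit cycles),
#'   `prepeaks` (bursts flagged as prepeaks) and `is_prepeak` (logical vector
#'   aligned with the input rows).
#' @export
classify_prepeaks <- function(long_bursts) {
  n <- nrow(long_bursts)
  is_pre <- logical(n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      dur <- long_bursts$duration[i]
      nxt <- long_bursts[i + 1L, ]
      if (dur >= 1 && dur <= 2 && nxt$duration > 2 &&
          (nxt$onset - long_bursts$offset[i]) <= 5)
        is_pre[i] <- TRUE
    }
  }
  list(cycle_defining = {
         out <- long_bursts[!is_pre, , drop = FALSE]; rownames(out) <- NULL; out
       },
       prepeaks = {
         out <- long_bursts[is_pre, , drop = FALSE]; rownames(out) <- NULL; out
       },
       is_prepeak = is_pre)
}

#' Build pyloric cycles from PD bursts
#'
#' One cycle per consecutive pair of PD burst onsets; the cycle period is the
#' onset-to-onset duration and its frequency the inverse. IC spikes are counted
#' in the half-open cycle `[onset_k, onset_{k+1})`. Cycles with fewer than
#' `cfg$control_ic_spike_max` (default 10) IC spikes are control cycles; the
#' control period is the mean over all control cycles of the incubation, and a
#' cycle is interrupted when its period reaches
#' `cfg$interruption_threshold` (default 150%) of that control mean.
#'
#' @param pd_bursts PD burst data frame from [detect_bursts()].
#' @param ic_train IC [spike_train()] (may be `NULL`: IC counts are then 0).
#' @param cfg a [gm_config()].
#' @return Data frame with columns `onset`, `period`, `frequency`,
#'   `ic_spike_count`, `is_control`, `pct_of_control`, `is_interrupted`.
#' @export
build_pyloric_cycles <- function(pd_bursts, ic_train = NULL,
                                 cfg = gm_config()) {
  empty <- data.frame(onset = numeric(), period = numeric(),
                      frequency = numeric(), ic_spike_count = integer(),
                      is_control = logical(), pct_of_control = numeric(),
                      is_interrupted = logical())
  if (nrow(pd_bursts) < 2L) {
    warning("fewer than 2 PD bursts; no pyloric cycles")
    return(empty)
  }
  onsets <- pd_bursts$onset
  period <- diff(onsets)
  onset <- onsets[-length(onsets)]
  ic_times <- if (is.null(ic_train)) numeric(0) else ic_train$times
  ic_count <- vapply(seq_along(onset), function(k)
    sum(ic_times >= onset[k] & ic_times < onsets[k + 1L]), integer(1))
  is_control <- ic_count < cfg$control_ic_spike_max
  ctrl_mean <- if (any(is_control)) mean(period[is_control]) else NA_real_
  pct <- 100 * period / ctrl_mean
  data.frame(onset = onset, period = period, frequency = 1 / period,
             ic_spike_count = ic_count, is_control = is_control,
             pct_of_control = pct,
             is_interrupted = !is.na(pct) &
               pct >= 100 * cfg$interruption_threshold)
}

#' Build gastric mill cycles from cycle-defining long IC bursts
#'
#' The gastric cycle period is the duration between the onsets of consecutive
#' cycle-defining long IC bursts (after prepeak removal,
#' [classify_prepeaks()]). Member bursts of other neurons are assigned to the
#' cycle containing their onset.
#'
#' @param cycle_bursts cycle-defining long IC burst data frame.
#' @param member_bursts optional named list of burst data frames (per neuron)
#'   to assign to cycles.
#' @return A list with `cycles` (data frame: `onset`, `period`,
#'   `ic_burst_duration`, `ic_burst_n_spikes`, `ic_burst_rate_hz`) and
#'   `members` (the member burst rows with an added `cycle` index, 1-based;
#'   bursts outside all cycles get `NA`).
#' @export
build_gastric_cycles <- function(cycle_bursts, member_bursts = NULL) {
  empty <- data.frame(onset = numeric(), period = numeric(),
                      ic_burst_duration = numeric(),
                      ic_burst_n_spikes = integer(),
                      ic_burst_rate_hz = numeric())
  if (nrow(cycle_bursts) < 2L) {
    warning("fewer than 2 cycle-defining long IC bursts; no gastric cycles")
    return(list(cycles = empty, members = NULL))
  }
  on <- cycle_bursts$onset
  k <- length(on) - 1L
  cycles <- data.frame(onset = on[-length(on)], period = diff(on),
                       ic_burst_duration = cycle_bursts$duration[seq_len(k)],
                       ic_burst_n_spikes = cycle_bursts$n_spikes[seq_len(k)],
                       ic_burst_rate_hz = cycle_bursts$rate_hz[seq_len(k)])
  members <- NULL
  if (!is.null(member_bursts)) {
    members <- do.call(rbind, lapply(member_bursts, function(b) b))
    if (!is.null(members) && nrow(members)) {
      idx <- findInterval(members$onset, on)
      idx[idx < 1L | idx > k] <- NA_integer_
      members$cycle <- idx
      rownames(members) <- NULL
    }
  }
  list(cycles = cycles, members = members)
}

#' Duty cycle
#'
#' Burst duration as a percentage of the cycle period; capped at 100% with a
#' warning when the burst outlasts the cycle.
#'
#' @param burst_duration,cycle_period seconds; `cycle_period > 0`.
#' @return Duty cycle in percent.
#' @export
#' @examples
#' duty_cycle(2.8, 14)  # 20
duty_cycle <- function(burst_duration, cycle_period) {
  stopifnot(all(cycle_period > 0), all(burst_duration >= 0))
  dc <- 100 * burst_duration / cycle_period
  if (any(dc > 100)) {
    warning("burst duration exceeds cycle period; duty cycle capped at 100%")
    dc <- pmin(dc, 100)
  }
  dc
}

#' Select pyloric cycles by IC spike load
#'
#' Keeps cycles with strictly more than `min_ic_spikes` IC spikes between
#' successive PD bursts (default 20), the input set for the repeated-measures
#' correlation between IC activity and pyloric period.
#'
#' @param cycles pyloric cycle data frame from [build_pyloric_cycles()].
#' @param min_ic_spikes strict lower bound on IC spike count.
#' @return The subset of cycles.
#' @export
cycles_with_ic_load <- function(cycles, min_ic_spikes = 20L) {
  out <- cycles[cycles$ic_spike_count > min_ic_spikes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Run burst detection and cycle construction for one recording over the
# analysis window [incubation_start + 60, incubation_start + duration).
# Internal workhorse shared by summarize_incubation, featurization and
# classification.
analyze_recording <- function(rec, cfg = gm_config()) {
  win <- list(start = rec$incubation_start + 60,
              stop = rec$incubation_start + rec$incubation_duration)
  out <- list(window = win)
  get_train <- function(nm) rec$trains[[nm]]
  # per-neuron bursts at the class ceiling, restricted to the analysis window
  out$bursts <- list()
  for (nm in names(rec$trains)) {
    b <- detect_bursts(get_train(nm), isi_ceiling(nm, FALSE, cfg))$bursts
    out$bursts[[nm]] <- bursts_in_window(b, win)
  }
  # gastric-mill-timed IC bursts (slow ceiling)
  ic <- get_train("IC")
  out$ic_gastric_bursts <- if (is.null(ic)) NULL else
    bursts_in_window(detect_bursts(ic, isi_ceiling("IC", TRUE, cfg))$bursts,
                     win)
  out$long_ic <- if (is.null(out$ic_gastric_bursts))
    NULL else long_ic_bursts(out$ic_gastric_bursts, cfg)
  if (!is.null(out$long_ic)) {
    pp <- classify_prepeaks(out$long_ic)
    out$prepeaks <- pp$prepeaks
    out$cycle_bursts <- pp$cycle_defining
  } else {
    out$prepeaks <- NULL
    out$cycle_bursts <- NULL
  }
  gm_members <- out$bursts[intersect(c("LG", "DG", "AM"), names(out$bursts))]
  out$gastric <- if (is.null(out$cycle_bursts) || nrow(out$cycle_bursts) < 2L)
    list(cycles = NULL, members = NULL)
  else suppressWarnings(build_gastric_cycles(out$cycle_bursts, gm_members))
  pd <- out$bursts[["PD"]]
  out$pyloric <- if (is.null(pd) || nrow(pd) < 2L) NULL else
    suppressWarnings(build_pyloric_cycles(pd, ic, cfg))
  out
}

#' Summarize an incubation
#'
#' Computes the per-incubation counts and mean burst/cycle parameters over the
#' analysis window (the incubation minus its first 60 s): number of long IC
#' bursts, number of interrupted pyloric cycles, gastric cycle period, IC
#' burst duration/rate/spike count/duty cycle, control pyloric period,
#' interruption (delay) duration and percent of control, and per-neuron (LG,
#' DG, AM) spikes per burst, rate, and burst duration. Prepeak bursts count
#' toward burst-count/duration/rate statistics but not toward the cycle
#' period.
#'
#' @param rec a [gm_recording()].
#' @param cfg a [gm_config()].
#' @return A one-row data frame of class `gm_incubation_summary`; undefined
#'   means are `NA`.
#' @export
summarize_incubation <- function(rec, cfg = gm_config()) {
  an <- analyze_recording(rec, cfg)
  long_all <- an$long_ic  # includes prepeaks for count/duration/rate stats
  cyc <- an$gastric$cycles
  py <- an$pyloric
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  neuron_stats <- function(nm) {
    b <- an$bursts[[nm]]
    if (is.null(b) || !nrow(b)) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(b$n_spikes), mean(b$rate_hz), mean(b$duration))
  }
  lg <- neuron_stats("LG"); dg <- neuron_stats("DG"); am <- neuron_stats("AM")
  n_long <- if (is.null(long_all)) 0L else nrow(long_all)
  n_int <- if (is.null(py)) 0L else sum(py$is_interrupted)
  ctrl <- if (is.null(py) || !any(py$is_control)) NA_real_ else
    mean(py$period[py$is_control])
  delays <- if (is.null(py)) numeric(0) else py$period[py$is_interrupted]
  duty <- if (is.null(cyc) || !nrow(cyc)) NA_real_ else
    mean(duty_cycle(cyc$ic_burst_duration, cyc$period))
  out <- data.frame(
    subject_id = rec$subject_id, condition = rec$condition,
    n_long_ic_bursts = n_long, n_interruptions = n_int,
    ic_spikes_per_long_burst = mean_or_na(long_all$n_spikes),
    ic_rate_hz = mean_or_na(long_all$rate_hz),
    ic_burst_duration_s = mean_or_na(long_all$duration),
    ic_duty_cycle_pct = duty,
    gm_cycle_period_s = if (is.null(cyc) || !nrow(cyc)) NA_real_ else
      mean(cyc$period),
    pr_control_period_s = ctrl,
    pr_delay_duration_s = mean_or_na(delays),
    pr_delay_pct_control = if (length(delays) && !is.na(ctrl))
      mean(100 * delays / ctrl) else NA_real_,
    lg_spikes_per_burst = lg[1], lg_rate_hz = lg[2], lg_burst_duration_s = lg[3],
    dg_spikes_per_burst = dg[1], dg_rate_hz = dg[2], dg_burst_duration_s = dg[3],
    am_spikes_per_burst = am[1], am_rate_hz = am[2], am_burst_duration_s = am[3])
  class(out) <- c("gm_incubation_summary", class(out))
  out
}
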