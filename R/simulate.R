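#' Rhythm specification for the synthetic generator
#'
#' Describes the rhythm state a synthetic recording should express. `FULL` is
#' a regular gastric mill rhythm: gastric cycles of ~13-20 s (default mean
#' 14 s, CV 0.18), each containing one long (>= 1 s) IC burst firing at
#' 21-28 Hz (default 24), a coordinated LG/DG/AM ensemble, and pyloric
#' interruptions during the long IC burst. `IRREGULAR` has long IC bursts but
#' cycle periods of >= 40 s (default mean 45 s, CV 0.37) with per-neuron
#' dropout. `NONE` carries only pyloric-timed activity; IC bursts all last
#' < 0.5 s.
#'
#' @param state one of "FULL", "IRREGULAR", "NONE".
#' @param gm_period_s mean gastric cycle period, s.
#' @param gm_period_cv coefficient of variation of the gastric period.
#' @param ic_long_burst_duration_s mean long IC burst duration, s.
#' @param ic_burst_rate_hz intraburst IC firing rate, Hz.
#' @param pyloric_period_s baseline pyloric cycle period, s.
#' @param pd_duty_cycle PD duty cycle (fraction of the pyloric period).
#' @param interruption_factor multiplier applied to the pyloric period while a
#'   long IC burst is in progress (>= 1.5).
#' @param prepeak_probability chance a gastric cycle is preceded by a 1-2 s
#'   prepeak IC burst.
#' @param dropout per-neuron probability that a gastric burst is skipped
#'   (IRREGULAR only).
#' @param seed integer RNG seed.
#' @return An object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(state = c("FULL", "IRREGULAR", "NONE"),
                        gm_period_s = NULL,
                        gm_period_cv = NULL,
                        ic_long_burst_duration_s = 2.5,
                        ic_burst_rate_hz = 24,
                        pyloric_period_s = 1.1,
                        pd_duty_cycle = 0.20,
                        interruption_factor = 1.8,
                        prepeak_probability = 0.2,
                        dropout = 0.3,
                        seed = 1L) {
  state <- match.arg(state)
  if (is.null(gm_period_s))
    gm_period_s <- switch(state, FULL = 14, IRREGULAR = 45, NONE = NA_real_)
  if (is.null(gm_period_cv))
    gm_period_cv <- switch(state, FULL = 0.18, IRREGULAR = 0.37,
                           NONE = NA_real_)
  stopifnot(ic_long_burst_duration_s > 0, ic_burst_rate_hz > 0,
            pyloric_period_s > 0, pd_duty_cycle > 0, pd_duty_cycle < 1,
            interruption_factor >= 1.5, prepeak_probability >= 0,
            prepeak_probability <= 1, dropout >= 0, dropout < 1)
  if (state == "FULL" && (gm_period_s < 13 || gm_period_s > 20))
    stop("FULL-state gastric period must lie in [13, 20] s")
  if (state == "IRREGULAR" && gm_period_s < 40)
    stop("IRREGULAR-state gastric period must be >= 40 s")
  structure(list(state = state, gm_period_s = gm_period_s,
                 gm_period_cv = gm_period_cv,
                 ic_long_burst_duration_s = ic_long_burst_duration_s,
                 ic_burst_rate_hz = ic_burst_rate_hz,
                 pyloric_period_s = pyloric_period_s,
                 pd_duty_cycle = pd_duty_cycle,
                 interruption_factor = interruption_factor,
                 prepeak_probability = prepeak_probability,
                 dropout = dropout, seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' @export
print.rhythm_spec <- function(x, ...) {
  cat(sprintf("<rhythm_spec> state %s, gastric period %g s (CV %g), seed %d\n",
              x$state, x$gm_period_s, x$gm_period_cv, x$seed))
  invisible(x)
}

# Regular intraburst spike grid with interior jitter; the first and last spike
# sit exactly on the burst bounds so detection recovers onset/offset exactly.
.burst_spikes <- function(onset, offset, rate_hz) {
  n <- max(2L, round((offset - onset) * rate_hz) + 1L)
  ts <- seq(onset, offset, length.out = n)
  if (n > 2L) {
    step <- (offset - onset) / (n - 1L)
    mid <- seq.int(2L, n - 1L)
    ts[mid] <- ts[mid] + stats::runif(length(mid), -0.15, 0.15) * step
  }
  ts
}

# Evaluate within a private RNG stream, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic recording with ground truth
#'
#' Emits spike trains for IC, PD, LPG, LG, DG and AM under the given rhythm
#' specification, together with the generating ground truth: true per-segment
#' categories, gastric cycle onsets, long IC burst intervals (prepeaks
#' flagged), pyloric cycle onsets with interruption flags, and per-neuron
#' burst intervals. Activity begins 60 s into the recording (the analysis
#' window) and the incubation starts at t = 0. The same spec and seed always
#' reproduce the identical recording.
#'
#' Within a gastric cycle the phase layout follows the canonical pattern of
#' this rhythm: the long IC burst occupies the first ~20% of the cycle, LG
#' bursts at cycle onset, AM tracks the IC burst, DG starts near the IC burst
#' end and terminates by the cycle midpoint, and the pyloric (PD) period is
#' stretched by `interruption_factor` while the long IC burst is in progress.
#'
#' @param spec a [rhythm_spec()].
#' @param duration_s recording duration, seconds (>= 300; >= 900 typical).
#' @return A list with elements `recording` (a [gm_recording()]) and `truth`
#'   (class `gm_ground_truth`).
#' @export
#' @examples
#' sim <- generate_recording(rhythm_spec("FULL", seed = 7), 900)
#' nrow(sim$truth$long_bursts)
generate_recording <- function(spec, duration_s = 900) {
  stopifnot(inherits(spec, "rhythm_spec"))
  if (duration_s < 300) stop("duration too short for a meaningful incubation")
  if (spec$state != "NONE" && duration_s < 60 + 2 * spec$gm_period_s)
    stop("duration too short for one gastric cycle")
  .with_seed(spec$seed, .generate_recording_impl(spec, duration_s))
}

.generate_recording_impl <- function(spec, duration_s) {
  st <- spec$state
  trains <- list(IC = numeric(0), PD = numeric(0), LPG = numeric(0),
                 LG = numeric(0), DG = numeric(0), AM = numeric(0))
  long_bursts <- data.frame(onset = numeric(), offset = numeric(),
                            duration = numeric(), is_prepeak = logical())
  member <- data.frame(neuron = character(), onset = numeric(),
                       offset = numeric())
  cycle_onsets <- numeric(0)

  ## --- gastric skeleton (FULL / IRREGULAR) ---------------------------------
  if (st != "NONE") {
    mu <- spec$gm_period_s
    sdev <- spec$gm_period_cv * mu
    t <- 61 + stats::runif(1, 0, 3)
    has_pre <- stats::runif(1) < spec$prepeak_probability
    emitted_idx <- 0L
    repeat {
      # burst duration; cycles carrying a prepeak need a > 2 s main burst so
      # the prepeak rule applies to them
      dur <- .clamp(stats::rnorm(1, spec$ic_long_burst_duration_s, 0.4),
                    if (has_pre) 2.1 else 1.5, 3.5)
      if (t + dur > duration_s - 1) break
      emit <- st == "FULL" || stats::runif(1) > 0.25  # intermittent IC bursts
      if (has_pre && emit) {
        g <- stats::runif(1, 2.2, 3.0)       # gap clears the 2 s ISI ceiling
        pdur <- stats::runif(1, 1.0, 1.5)
        p_on <- t - g - pdur
        trains$IC <- c(trains$IC, .burst_spikes(p_on, p_on + pdur,
                                                spec$ic_burst_rate_hz))
        long_bursts <- rbind(long_bursts,
                             data.frame(onset = p_on, offset = p_on + pdur,
                                        duration = pdur, is_prepeak = TRUE))
      }
      if (emit) {
        emitted_idx <- emitted_idx + 1L
        trains$IC <- c(trains$IC, .burst_spikes(t, t + dur,
                                                spec$ic_burst_rate_hz))
        long_bursts <- rbind(long_bursts,
                             data.frame(onset = t, offset = t + dur,
                                        duration = dur, is_prepeak = FALSE))
        cycle_onsets <- c(cycle_onsets, t)
      }
      # next period; floors keep bursts separable and the prepeak rule
      # unambiguous (a short main burst never sits within 5 s of the next)
      has_pre_next <- stats::runif(1) < spec$prepeak_probability
      p <- stats::rnorm(1, mu, sdev)
      p <- max(p, dur + if (has_pre_next) 7.0 else 5.6)
      if (emit) {
        layout_p <- min(p, duration_s - 0.5 - t)
        drop_lg <- st == "IRREGULAR" &&
          (emitted_idx %% 2L == 0L || stats::runif(1) < spec$dropout)
        drop_dg <- st == "IRREGULAR" && stats::runif(1) < spec$dropout
        drop_am <- st == "IRREGULAR" && stats::runif(1) < spec$dropout
        if (!drop_lg) {
          lg_on <- t + 0.05
          lg_off <- min(lg_on + 2.0, t + layout_p - 0.5)
          if (lg_off - lg_on > 0.4) {
            trains$LG <- c(trains$LG, .burst_spikes(lg_on, lg_off, 6))
            member <- rbind(member, data.frame(neuron = "LG", onset = lg_on,
                                               offset = lg_off))
          }
        }
        if (!drop_am) {
          am_on <- t + 0.02
          am_off <- min(t + dur, t + layout_p - 0.3)
          if (am_off - am_on > 0.4) {
            trains$AM <- c(trains$AM, .burst_spikes(am_on, am_off, 7.7))
            member <- rbind(member, data.frame(neuron = "AM", onset = am_on,
                                               offset = am_off))
          }
        }
        if (!drop_dg) {
          dg_on <- t + dur + 0.2
          dg_off <- max(dg_on + 1.0, t + 0.45 * layout_p)
          dg_off <- min(dg_off, t + layout_p - 0.5, duration_s - 0.5)
          if (dg_off - dg_on > 0.4) {
            trains$DG <- c(trains$DG, .burst_spikes(dg_on, dg_off, 14))
            member <- rbind(member, data.frame(neuron = "DG", onset = dg_on,
                                               offset = dg_off))
          }
        }
      }
      t <- t + p
      has_pre <- has_pre_next
    }
  }

  ## --- pyloric skeleton (all states) ---------------------------------------
  base <- spec$pyloric_period_s
  pd_dur <- spec$pd_duty_cycle * base
  li <- long_bursts[!duplicated(long_bursts), , drop = FALSE]
  overlap_len <- function(a, b) {
    if (!nrow(li)) return(0)
    sum(pmax(0, pmin(b, li$offset) - pmax(a, li$onset)))
  }
  t <- 60.3 + stats::runif(1, 0, 0.5)
  pd_on <- numeric(0); pd_per <- numeric(0); pd_int <- logical(0)
  k <- 0L
  repeat {
    eps <- .clamp(stats::rnorm(1, 0, 0.01), -0.03, 0.03)
    p <- base * (1 + eps)
    interrupted <- overlap_len(t, t + p) >= 0.6
    if (interrupted) p <- base * spec$interruption_factor
    if (t + pd_dur > duration_s - 0.5) break
    trains$PD <- c(trains$PD, .burst_spikes(t, t + pd_dur, 4 / pd_dur))
    pd_on <- c(pd_on, t); pd_per <- c(pd_per, p)
    pd_int <- c(pd_int, interrupted)
    k <- k + 1L
    # LPG fires in antiphase; its duty doubles through mid gastric cycle
    lpg_duty <- pd_dur
    if (st != "NONE" && length(cycle_onsets)) {
      ci <- findInterval(t, cycle_onsets)
      if (ci >= 1L && ci < length(cycle_onsets)) {
        per <- cycle_onsets[ci + 1L] - cycle_onsets[ci]
        ph <- (t - cycle_onsets[ci]) / per
        if (ph >= 0.25 && ph <= 0.6) lpg_duty <- 2 * pd_dur
      }
    }
    lpg_on <- t + 0.5 * p
    lpg_off <- min(lpg_on + lpg_duty, duration_s - 0.2)
    if (lpg_off - lpg_on > 0.05)
      trains$LPG <- c(trains$LPG, .burst_spikes(lpg_on, lpg_off, 20))
    # NONE: a brief pyloric-timed IC burst every third cycle, spaced so the
    # 2 s gastric ceiling never merges them into a spurious long burst
    if (st == "NONE" && k %% 3L == 0L) {
      ic_on <- t + 0.6 * p
      if (ic_on + 0.18 <= duration_s - 0.2)
        trains$IC <- c(trains$IC, .burst_spikes(ic_on, ic_on + 0.18, 22))
    }
    t <- t + p
  }
  # sparse tonic background for silent gastric neurons in NONE
  if (st == "NONE") {
    for (nm in c("LG", "DG", "AM")) {
      tt <- 62 + stats::runif(1, 0, 2)
      sp <- numeric(0)
      while (tt < duration_s - 1) {
        sp <- c(sp, tt)
        tt <- tt + stats::runif(1, 3, 8)
      }
      trains[[nm]] <- c(trains[[nm]], sp)
    }
  }

  pyloric <- if (length(pd_on) >= 2L)
    data.frame(onset = pd_on[-length(pd_on)], period = diff(pd_on),
               interrupted = pd_int[-length(pd_int)])
  else data.frame(onset = numeric(), period = numeric(),
                  interrupted = logical())

  sts <- lapply(names(trains), function(nm) {
    ts <- sort(trains[[nm]])
    ts <- ts[!duplicated(ts)]
    spike_train(nm, ts, 0, duration_s)
  })
  names(sts) <- names(trains)
  rec <- gm_recording(sts, subject_id = sprintf("sim-%s-%d", st, spec$seed),
                      condition = st, incubation_start = 0,
                      incubation_duration = duration_s)
  long_bursts <- long_bursts[order(long_bursts$onset), , drop = FALSE]
  rownames(long_bursts) <- NULL
  truth <- structure(list(
    state = st,
    segment_categories = rep(switch(st, FULL = "GMR", IRREGULAR = "IRREGULAR",
                                    NONE = "NONE"),
                             nrow(suppressWarnings(
                               segment_windows(0, duration = duration_s)))),
    cycle_onsets = cycle_onsets,
    long_bursts = long_bursts,
    pyloric = pyloric,
    member_bursts = member,
    ic_rate_hz = spec$ic_burst_rate_hz,
    spec = spec), class = "gm_ground_truth")
  list(recording = rec, truth = truth)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a batch of recordings for a synthetic condition
#'
#' Assigns rhythm states to subjects deterministically from the requested mix
#' (largest-remainder apportionment, states in the order FULL, IRREGULAR,
#' NONE) and generates each recording from its own RNG stream seeded by the
#' global seed and the subject index, so batches are reproducible element-wise.
#'
#' @param n_subjects number of recordings.
#' @param mix named numeric vector of state proportions summing to 1 (names
#'   from FULL, IRREGULAR, NONE).
#' @param seed global integer seed.
#' @param duration_s per-recording duration, seconds.
#' @param ... further arguments passed to [rhythm_spec()].
#' @return A list of `list(recording, truth)` pairs.
#' @export
generate_condition_batch <- function(n_subjects, mix = c(FULL = 1),
                                     seed = 1L, duration_s = 900, ...) {
  stopifnot(n_subjects >= 0)
  if (any(mix < 0)) stop("mix proportions must be nonnegative")
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  states <- c("FULL", "IRREGULAR", "NONE")
  bad <- setdiff(names(mix), states)
  if (length(bad)) stop("unknown state(s) in mix: ", paste(bad, collapse = ", "))
  if (n_subjects == 0L) return(list())
  prop <- stats::setNames(mix[match(states, names(mix))], states)
  prop[is.na(prop)] <- 0
  base_n <- floor(prop * n_subjects)
  rem <- n_subjects - sum(base_n)
  if (rem > 0) {
    frac <- prop * n_subjects - base_n
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base_n[add] <- base_n[add] + 1L
  }
  assign_states <- rep(states, times = base_n)
  lapply(seq_len(n_subjects), function(i) {
    sub_seed <- (as.integer(seed) * 1009L + i) %% 2147483587L
    sp <- rhythm_spec(assign_states[i], seed = sub_seed, ...)
    sim <- generate_recording(sp, duration_s)
    sim$recording$subject_id <- sprintf("sub%02d", i)
    sim
  })
}

#' Segment classification counts for the four incubation conditions
#'
#' The published per-condition 200-s segment classification counts used as the
#' worked-example input to the odds-ratio statistics: per condition, the
#' number of segments with a gastric mill rhythm and the number without
#' (irregular and no-rhythm segments combined).
#'
#' @return A data frame with columns `condition`, `n_gmr`, `n_non`, `n_total`.
#' @export
#' @examples
#' gmr_segment_counts()
gmr_segment_counts <- function() {
  out <- data.frame(
    condition = c("1uM-S", "1uM-UH", "1uM-FH", "10uM-S"),
    n_gmr = c(9L, 21L, 38L, 42L),
    n_non = c(87L, 19L, 6L, 22L))
  out$n_total <- out$n_gmr + out$n_non
  out
}
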