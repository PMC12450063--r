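burst_df <- function(onsets, durations, rate = 20) {
  n <- pmax(2L, round(durations * rate) + 1L)
  data.frame(neuron = "IC", onset = onsets, offset = onsets + durations,
             n_spikes = n, duration = durations,
             rate_hz = (n - 1) / durations)
}

test_that("long IC bursts are selected inclusively at 1 s", {
  b <- burst_df(c(0, 10, 20), c(0.2, 1.0, 2.5))
  out <- long_ic_bursts(b)
  expect_equal(out$duration, c(1.0, 2.5))
  expect_equal(nrow(long_ic_bursts(burst_df(c(0, 10), c(0.4, 0.9)))), 0L)
})

test_that("prepeak bursts attach to the preceding cycle", {
  # 1.5 s burst, then a 3 s burst starting 2 s after its offset
  b <- burst_df(c(0, 3.5), c(1.5, 3.0))
  pp <- classify_prepeaks(b)
  expect_equal(pp$is_prepeak, c(TRUE, FALSE))
  expect_equal(pp$cycle_defining$onset, 3.5)
  # successor not longer than 2 s: no prepeak
  pp <- classify_prepeaks(burst_df(c(0, 3.5), c(1.5, 1.5)))
  expect_equal(pp$is_prepeak, c(FALSE, FALSE))
  # successor beyond 5 s: no prepeak
  pp <- classify_prepeaks(burst_df(c(0, 7.6), c(1.5, 3.0)))
  expect_equal(pp$is_prepeak, c(FALSE, FALSE))
})

test_that("pyloric cycles carry IC counts, control flags and interruptions", {
  pd <- data.frame(neuron = "PD", onset = c(0, 1, 2.6), offset = c(0, 1, 2.6) + 0.2,
                   n_spikes = 5L, duration = 0.2, rate_hz = 20)
  ic <- make_train(c(seq(1.05, 2.55, length.out = 30)), "IC")
  cyc <- build_pyloric_cycles(pd, ic)
  expect_equal(cyc$period, c(1, 1.6))
  expect_equal(cyc$frequency, 1 / cyc$period)
  expect_equal(cyc$ic_spike_count, c(0L, 30L))
  expect_equal(cyc$is_control, c(TRUE, FALSE))
  # control mean 1.0 s -> 160% of control, interrupted
  expect_equal(cyc$pct_of_control, c(100, 160))
  expect_equal(cyc$is_interrupted, c(FALSE, TRUE))
  # 140% is not an interruption
  pd2 <- pd; pd2$onset <- c(0, 1, 2.4); pd2$offset <- pd2$onset + 0.2
  cyc2 <- build_pyloric_cycles(pd2, ic)
  expect_equal(cyc2$pct_of_control, c(100, 140))
  expect_false(cyc2$is_interrupted[2])
  expect_warning(out <- build_pyloric_cycles(pd[1, ], ic), "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("gastric cycle periods come from consecutive long-burst onsets", {
  b <- burst_df(c(10, 24, 38), c(2.5, 2.5, 2.5))
  g <- build_gastric_cycles(b)
  expect_equal(g$cycles$period, c(14, 14))
  # periods telescope to last onset minus first onset
  expect_equal(sum(g$cycles$period), 38 - 10)
  expect_warning(g1 <- build_gastric_cycles(b[1, ]), "fewer than 2")
  expect_equal(nrow(g1$cycles), 0L)
  # member bursts assigned by onset
  lg <- data.frame(neuron = "LG", onset = c(11, 25, 50), offset = c(12, 26, 51),
                   n_spikes = 5L, duration = 1, rate_hz = 4)
  g2 <- build_gastric_cycles(b, list(LG = lg))
  expect_equal(g2$members$cycle, c(1L, 2L, NA_integer_))
})

test_that("duty cycle is burst duration over period, capped at 100%", {
  expect_equal(duty_cycle(2.8, 14), 20)
  expect_equal(duty_cycle(0, 14), 0)
  expect_equal(duty_cycle(14, 14), 100)
  expect_warning(v <- duty_cycle(15, 14), "capped")
  expect_equal(v, 100)
})

test_that("IC-load selection is strictly greater-than", {
  cyc <- data.frame(ic_spike_count = c(5L, 21L, 40L))
  expect_equal(nrow(cycles_with_ic_load(cyc, 20)), 2L)
  expect_equal(nrow(cycles_with_ic_load(cyc, 0)), 3L)
  expect_equal(nrow(cycles_with_ic_load(cyc[0, , drop = FALSE], 20)), 0L)
})

test_that("incubation summaries recover generator ground truth", {
  sim <- generate_recording(rhythm_spec("FULL", seed = 7), 900)
  s <- summarize_incubation(sim$recording)
  expect_equal(s$n_long_ic_bursts, nrow(sim$truth$long_bursts))
  expect_equal(s$n_interruptions, sum(sim$truth$pyloric$interrupted))
  expect_lt(abs(s$ic_rate_hz - 24) / 24, 0.1)
  expect_lt(abs(s$gm_cycle_period_s - 14) / 14, 0.05)
  none <- summarize_incubation(generate_recording(rhythm_spec("NONE",
                                                              seed = 9),
                                                  900)$recording)
  expect_equal(none$n_long_ic_bursts, 0L)
  expect_equal(none$n_interruptions, 0L)
})

test_that("interruption detection matches ground truth indices exactly", {
  for (seed in c(1, 2, 3)) {
    sim <- generate_recording(rhythm_spec("FULL", seed = seed,
                                          interruption_factor = 1.8), 900)
    an <- gastricmill:::analyze_recording(sim$recording)
    expect_equal(an$pyloric$is_interrupted, sim$truth$pyloric$interrupted)
  }
})

test_that("interrupted count is monotone in the threshold and control set in
           its cutoff", {
  sim <- generate_recording(rhythm_spec("FULL", seed = 4), 900)
  pd <- gastricmill:::analyze_recording(sim$recording)$bursts$PD
  ic <- sim$recording$trains$IC
  thresholds <- c(1.2, 1.5, 1.8, 2.5)
  n_int <- vapply(thresholds, function(th)
    sum(build_pyloric_cycles(pd, ic,
                             gm_config(interruption_threshold = th))$is_interrupted),
    integer(1))
  expect_true(all(diff(n_int) <= 0))
  cutoffs <- c(5L, 10L, 20L, 50L)
  n_ctrl <- vapply(cutoffs, function(cm)
    sum(build_pyloric_cycles(pd, ic,
                             gm_config(control_ic_spike_max = cm))$is_control),
    integer(1))
  expect_true(all(diff(n_ctrl) >= 0))
})
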