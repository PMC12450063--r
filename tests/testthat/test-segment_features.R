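test_that("burstiness follows the sorted-ISI gap formula", {
  expect_equal(burstiness(c(0.1, 0.1, 0.2, 1.8)), 1.6 / 1.8)
  expect_equal(burstiness(c(0.5, 0.5, 0.5)), 0)
  expect_equal(burstiness(c(0.1, 1.0)), 0.9)
  expect_true(is.na(burstiness(0.5)))
  # always in [0, 1] on random inputs
  set.seed(1)
  for (i in 1:50) {
    v <- burstiness(runif(sample(2:30, 1), 0.01, 5))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("second-to-first-order ISI ratio vanishes for regular spiking", {
  expect_equal(isi_order_ratio(seq(0, 10, by = 0.5)), 0)
  expect_equal(isi_order_ratio(c(0, 1, 3)), 1 / 1.5)
  expect_true(is.na(isi_order_ratio(c(0, 1))))
})

test_that("max ISI ratio is max over second max", {
  expect_equal(max_isi_ratio(c(0.1, 0.2, 2.0)), 10)
  expect_equal(max_isi_ratio(c(0.3, 0.3, 0.3)), 1)
  expect_equal(max_isi_ratio(c(3.0, 1.0)), 3)
  expect_true(is.na(max_isi_ratio(0.5)))
})

test_that("deciles match a first-principles interpolation oracle", {
  p <- seq(0.1, 1, by = 0.1)
  expect_equal(deciles(1:100), brute_force_quantile(1:100, p))
  expect_equal(deciles(1:100)[10], 100)
  expect_equal(deciles(1:100)[1], 10.9)
  expect_equal(deciles(7), rep(7, 10))
  expect_true(all(diff(deciles(c(2, 9))) >= 0))
  set.seed(2)
  for (i in 1:25) {
    x <- rnorm(sample(2:50, 1))
    expect_equal(deciles(x), brute_force_quantile(x, p))
    expect_true(all(diff(deciles(x)) >= -1e-12))
  }
  expect_true(all(is.na(deciles(numeric(0)))))
})

test_that("spike phases are measured from the IC burst onset", {
  cyc <- data.frame(onset = 0, period = 10)
  expect_equal(phase_of_spikes(2.5, cyc), 0.25)
  expect_equal(phase_of_spikes(0, cyc), 0)
  expect_length(phase_of_spikes(12, cyc), 0L)
  cyc2 <- data.frame(onset = c(0, 10), period = c(10, 12))
  expect_equal(phase_of_spikes(c(2.5, 13), cyc2), c(0.25, 0.25))
})

test_that("segment feature vectors are fixed-length with valid blocks", {
  sim <- generate_recording(rhythm_spec("FULL", seed = 8), 900)
  w <- segment_windows(sim$recording)[1, ]
  v <- featurize_segment(sim$recording, w)
  expect_length(v, 120L)
  expect_true(all(grepl("^(IC|PD|LG|DG|AM)_", names(v))))
  for (nm in c("IC", "PD", "LG", "DG", "AM")) {
    dec <- v[paste0(nm, "_isi_d", 1:10)]
    if (!anyNA(dec)) expect_true(all(diff(dec) >= -1e-12))
    b <- v[paste0(nm, "_burstiness")]
    if (!is.na(b)) { expect_gte(b, 0); expect_lte(b, 1) }
    mr <- v[paste0(nm, "_max_ratio")]
    if (!is.na(mr)) expect_gte(mr, 1)
  }
  # same input, same output
  expect_identical(v, featurize_segment(sim$recording, w))
  # an empty window yields an all-sentinel vector
  v0 <- featurize_segment(sim$recording, list(index = 0, start = 2, stop = 20))
  expect_true(all(is.na(v0)))
})

test_that("FULL and NONE segments separate most strongly on IC structure", {
  f_full <- featurize_segment(
    generate_recording(rhythm_spec("FULL", seed = 3), 900)$recording,
    data.frame(index = 0, start = 60, stop = 260))
  f_none <- featurize_segment(
    generate_recording(rhythm_spec("NONE", seed = 3), 900)$recording,
    data.frame(index = 0, start = 60, stop = 260))
  # the IC block separates the states: burstiness contrasts sharply (NONE's
  # isolated brief bursts sit across ~3 s gaps; FULL's interburst gaps form a
  # broad continuum), and the top ISI deciles dwarf the NONE ones
  expect_gt(abs(f_full["IC_burstiness"] - f_none["IC_burstiness"]), 0.2)
  expect_gt(f_none["IC_burstiness"], 0.9)
  expect_gt(f_full["IC_isi_d10"], 2 * f_none["IC_isi_d10"])
  # phase structure exists only when gastric cycles exist
  expect_false(anyNA(f_full[paste0("IC_phase_d", 1:10)]))
  expect_true(all(is.na(f_none[paste0("IC_phase_d", 1:10)])))
})

test_that("rule-based classification recovers generator states", {
  for (st in c("FULL", "IRREGULAR", "NONE")) {
    sim <- generate_recording(rhythm_spec(st, seed = 12), 900)
    wins <- segment_windows(sim$recording)
    an <- gastricmill:::analyze_recording(sim$recording)
    got <- vapply(seq_len(nrow(wins)), function(i)
      rule_based_category(sim$recording, wins[i, ], analysis = an),
      character(1))
    expect_equal(got, sim$truth$segment_categories)
  }
})

test_that("transition bookkeeping counts pairs, persistence and jumps", {
  tt <- transition_table(rep("NONE", 4))
  expect_equal(tt$counts["NONE", "NONE"], 3L)
  expect_true(tt$persistence)
  tt2 <- transition_table(list(rep("GMR", 4), c("GMR", "NONE")))
  expect_equal(tt2$persistence, c(TRUE, FALSE))
  expect_equal(tt2$n_nonadjacent, 1L)
  expect_equal(sum(tt2$counts), 4L)
})
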