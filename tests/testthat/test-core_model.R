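test_that("segment windows cover 800 s after the 60 s exclusion", {
  w <- segment_windows(0, duration = 900)
  expect_equal(nrow(w), 4L)
  expect_equal(w$start, c(60, 260, 460, 660))
  expect_equal(w$stop, c(260, 460, 660, 860))
  expect_equal(sum(w$stop - w$start), 800)
  # no overlap
  expect_true(all(w$start[-1] == w$stop[-4]))
  # coverage fraction of the post-60 s incubation
  expect_equal(sum(w$stop - w$start) / (900 - 60), 800 / 840)
})

test_that("segment windows translate with incubation start and truncate", {
  w <- segment_windows(100, duration = 900)
  expect_equal(w$start, c(60, 260, 460, 660) + 100)
  expect_warning(w2 <- segment_windows(0, duration = 500), "2 segment")
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$stop, c(260, 460))
  expect_error(segment_windows(0, duration = 250), "too short")
})

test_that("slice_train uses half-open windows", {
  tr <- make_train(c(59, 60, 259.9, 260), "PD")
  out <- slice_train(tr, list(start = 60, stop = 260))
  expect_equal(out$times, c(60, 259.9))
  expect_equal(slice_train(make_train(numeric(0), "PD", pad = 300),
                           list(start = 60, stop = 260))$times, numeric(0))
  expect_equal(slice_train(tr, list(start = 1000, stop = 1200))$times,
               numeric(0))
})

test_that("spike train validation rejects disorder and out-of-window times", {
  expect_error(spike_train("PD", c(0.2, 0.1), 0, 1), "not strictly increasing")
  expect_error(spike_train("PD", c(0.1, 0.1), 0, 1), "not strictly increasing")
  expect_error(spike_train("PD", c(0.1, 2), 0, 1), "outside")
  expect_error(spike_train("XX", 0.1, 0, 1))
})

test_that("recording round-trips through CSV and manifest", {
  td <- withr::local_tempdir()
  csv <- file.path(td, "spikes.csv"); man <- file.path(td, "manifest.yaml")
  writeLines(c("neuron,time_s", "PD,0.1", "PD,0.2", "IC,0.15"), csv)
  yaml::write_yaml(list(subject_id = "s1", condition = "saline",
                        incubation_start_s = 0,
                        incubation_duration_s = 900), man)
  rec <- read_recording(csv, man)
  expect_length(rec$trains, 2L)
  expect_equal(rec$trains$PD$times, c(0.1, 0.2))
  expect_equal(rec$condition, "saline")
  # write-read identity
  csv2 <- file.path(td, "out.csv"); man2 <- file.path(td, "out.json")
  write_recording(rec, csv2, man2)
  rec2 <- read_recording(csv2, man2)
  expect_equal(rec2$trains$PD$times, rec$trains$PD$times)
  expect_equal(rec2$trains$IC$times, rec$trains$IC$times)
  expect_equal(rec2$subject_id, rec$subject_id)
})

test_that("reader flags empty files, bad labels and duplicate times", {
  td <- withr::local_tempdir()
  man <- file.path(td, "m.json")
  jsonlite::write_json(list(subject_id = "s", condition = "c",
                            incubation_start_s = 0), man, auto_unbox = TRUE)
  csv <- file.path(td, "e.csv")
  writeLines("neuron,time_s", csv)
  expect_message(rec <- read_recording(csv, man), "zero trains")
  expect_length(rec$trains, 0L)
  writeLines(c("neuron,time_s", "XX,0.1"), csv)
  expect_error(read_recording(csv, man), "unknown neuron")
  writeLines(c("neuron,time_s", "PD,0.1", "PD,0.1"), csv)
  expect_error(read_recording(csv, man), "PD")
  writeLines(c("cell,time_s", "PD,0.1"), csv)
  expect_error(read_recording(csv, man), "neuron,time_s")
})

test_that("write_results emits CSVs plus a stats JSON and round-trips", {
  td <- withr::local_tempdir()
  cls <- data.frame(subject = letters[1:4], category = c("GMR", "NONE",
                                                         "GMR", "IRREGULAR"))
  feats <- data.frame(a = c(pi, exp(1)), b = c(1L, 2L))
  paths <- write_results(list(classification = cls, features = feats,
                              stats = list()), td)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(td, "classification.csv"))
  expect_equal(nrow(back), 4L)
  fb <- utils::read.csv(file.path(td, "features.csv"))
  expect_equal(fb$b, feats$b)
  expect_equal(fb$a, feats$a, tolerance = 1e-12)
  js <- jsonlite::read_json(file.path(td, "stats.json"))
  expect_length(js, 0L)
})

test_that("windowing and per-segment statistics are translation equivariant", {
  sim <- generate_recording(rhythm_spec("FULL", seed = 21), 900)
  rec <- sim$recording
  delta <- 137.25
  shifted_trains <- lapply(rec$trains, function(tr)
    spike_train(tr$neuron, tr$times + delta, tr$t_start + delta,
                tr$t_stop + delta))
  rec2 <- gm_recording(shifted_trains, rec$subject_id, rec$condition,
                       rec$incubation_start + delta,
                       rec$incubation_duration)
  w1 <- segment_windows(rec); w2 <- segment_windows(rec2)
  expect_equal(w2$start, w1$start + delta)
  s1 <- summarize_incubation(rec); s2 <- summarize_incubation(rec2)
  num <- vapply(s1, is.numeric, logical(1))
  expect_equal(as.numeric(s1[num]), as.numeric(s2[num]), tolerance = 1e-9)
  f1 <- featurize_segment(rec, w1[1, ])
  f2 <- featurize_segment(rec2, w2[1, ])
  expect_equal(unname(f1), unname(f2), tolerance = 1e-9)
})
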