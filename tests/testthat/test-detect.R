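# Spike-and-wave discharge detection: background estimation, the
# amplitude/cycle acceptance criteria, boundary accuracy, invariances,
# and the review-export path.

test_that("background is stable on stationary noise and robust to a burst", {
  b <- burst_recording(duration_s = 300, seed = 31)
  bg <- estimate_background(b$rec, b$hyp)
  expect_true(all(bg > 0))
  expect_lt(stats::sd(bg) / mean(bg), 0.10)

  b2 <- burst_recording(duration_s = 300, seed = 31,
                        bursts = list(list(onset_s = 150, offset_s = 152,
                                           freq = 7, amp = 100)))
  bg2 <- estimate_background(b2$rec, b2$hyp)
  expect_lt(max(abs(bg2 - bg)) / mean(bg), 0.05)
})

test_that("an injected 2-s 6.7 Hz discharge is found with tight boundaries", {
  # square envelope: boundary accuracy is judged on the discharge proper,
  # not on ramp cycles that sit below the amplitude criterion by design
  b <- burst_recording(
    duration_s = 300, seed = 32,
    bursts = list(list(onset_s = 150, offset_s = 152, freq = 6.7, amp = 55,
                       amp2 = 25, freq2 = 13.3, taper = 0))
  )
  ev <- detect_swd(b$rec, b$hyp)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 150), 0.1)
  expect_lt(abs(ev$offset_s - 152), 0.1)
  expect_gte(ev$n_cycles, 13L)
  expect_gte(ev$peak_amplitude_ratio, 1.5)
})

test_that("a 3-cycle burst is rejected by the cycle criterion", {
  b <- burst_recording(
    duration_s = 300, seed = 33,
    bursts = list(list(onset_s = 150, offset_s = 150 + 3 / 6.7, freq = 6.7,
                       amp = 120, amp2 = 54, freq2 = 13.3))
  )
  ev <- detect_swd(b$rec, b$hyp)
  expect_equal(nrow(ev), 0L)
})

test_that("a low-amplitude burst is rejected by the 1.5x criterion", {
  # in-band background envelope of white noise (sd 20) at 100 Hz is ~14 uV;
  # a 10-cycle burst at ~1.2x that level must not be accepted
  b <- burst_recording(
    duration_s = 300, seed = 34,
    bursts = list(list(onset_s = 150, offset_s = 150 + 10 / 6.7, freq = 6.7,
                       amp = 17, amp2 = 7.7, freq2 = 13.3))
  )
  ev <- detect_swd(b$rec, b$hyp)
  expect_equal(nrow(ev), 0L)
})

test_that("raising the threshold factor never yields more events", {
  bursts <- lapply(c(50, 120, 190, 260), function(t0)
    list(onset_s = t0, offset_s = t0 + 2, freq = 6.7, amp = 45,
         amp2 = 20, freq2 = 13.3))
  b <- burst_recording(duration_s = 320, seed = 35, bursts = bursts)
  n <- vapply(c(1.5, 2.0, 2.8, 4.0), function(tf) {
    nrow(detect_swd(b$rec, b$hyp, detection_params(threshold_factor = tf)))
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("detection is invariant under amplitude scaling of the recording", {
  b <- burst_recording(
    duration_s = 300, seed = 36,
    bursts = list(list(onset_s = 100, offset_s = 102.2, freq = 6.7, amp = 70,
                       amp2 = 32, freq2 = 13.3),
                  list(onset_s = 200, offset_s = 201.5, freq = 6.7, amp = 70,
                       amp2 = 32, freq2 = 13.3))
  )
  ev1 <- detect_swd(b$rec, b$hyp)
  b$rec$channels[[1]]$samples <- b$rec$channels[[1]]$samples * 10
  ev10 <- detect_swd(b$rec, b$hyp)
  expect_equal(ev1$onset_s, ev10$onset_s)
  expect_equal(ev1$offset_s, ev10$offset_s)
  expect_equal(ev1$n_cycles, ev10$n_cycles)
})

test_that("every accepted event lies within a permissive candidate region", {
  b <- burst_recording(
    duration_s = 300, seed = 37,
    bursts = list(list(onset_s = 80, offset_s = 82, freq = 6.7, amp = 60,
                       amp2 = 27, freq2 = 13.3))
  )
  ev <- detect_swd(b$rec, b$hyp, return_candidates = TRUE)
  cand <- attr(ev, "candidates")
  for (i in seq_len(nrow(ev))) {
    expect_true(any(cand$onset_s <= ev$onset_s[i] + 0.6 &
                      cand$offset_s >= ev$offset_s[i] - 0.6))
  }
})

test_that("zero signal produces no events rather than an error", {
  fs <- 100
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal",
              samples = numeric(120 * fs)),
         list(name = "EMG nuchal", role = "EMG", samples = numeric(120 * fs))),
    fs = fs)
  hyp <- hypnogram(rep("WAKE", 12))
  ev <- detect_swd(rec, hyp)
  expect_equal(nrow(ev), 0L)
})

test_that("detection matching reports recall, precision and onset error", {
  truth <- event_table(c(10, 50, 90), c(12, 52.5, 91.5), channel = "ch",
                       provenance = "ground_truth")
  same <- evaluate_detection(truth, truth)
  expect_equal(same$recall, 1)
  expect_equal(same$precision, 1)
  expect_equal(same$onset_mae_s, 0)

  shifted <- event_table(c(10.2, 50.2, 90.2), c(12.2, 52.7, 91.7),
                         channel = "ch", provenance = "detected")
  ev <- evaluate_detection(shifted, truth)
  expect_equal(ev$recall, 1)
  expect_equal(ev$onset_mae_s, 0.2, tolerance = 1e-9)
})

test_that("review export writes snippets plus a template and curation filters", {
  b <- burst_recording(
    duration_s = 200, seed = 38,
    bursts = lapply(c(50, 100, 150), function(t0)
      list(onset_s = t0, offset_s = t0 + 2, freq = 6.7, amp = 60,
           amp2 = 27, freq2 = 13.3))
  )
  ev <- detect_swd(b$rec, b$hyp)
  expect_equal(nrow(ev), 3L)
  dir <- file.path(tempdir(), "review")
  export_review(b$rec, ev, dir)
  expect_length(list.files(dir, pattern = "^event_.*csv$"), 3L)
  tmpl <- utils::read.csv(file.path(dir, "review_template.csv"))
  expect_equal(nrow(tmpl), 3L)
  tmpl$decision[2] <- "reject"
  cur <- apply_review(ev, tmpl)
  expect_equal(nrow(cur), 2L)
  expect_true(all(cur$provenance == "curated"))
  expect_warning(export_review(b$rec, event_table(), tempfile()), "no events")
})
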