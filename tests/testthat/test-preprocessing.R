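# Acquisition-chain filtering and artifact tagging.

test_that("the notch removes a 50 Hz line by at least 20 dB", {
  fs <- 400
  t <- (0:(30 * fs - 1)) / fs
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal",
              samples = sin(2 * pi * 50 * t)),
         list(name = "EMG nuchal", role = "EMG", samples = 0 * t)),
    fs = fs
  )
  out <- apply_acquisition_filters(rec, filter_spec())
  rms_in <- sqrt(mean(rec$channels[[1]]$samples^2))
  rms_out <- sqrt(mean(out$channels[[1]]$samples^2))
  expect_lt(20 * log10(rms_out / rms_in), -20)
})

test_that("slow drift is removed by the EEG high-pass", {
  fs <- 400
  t <- (0:(120 * fs - 1)) / fs
  drift <- 100 * sin(2 * pi * 0.05 * t)
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = drift),
         list(name = "EMG nuchal", role = "EMG", samples = 0 * t)),
    fs = fs
  )
  out <- apply_acquisition_filters(rec, filter_spec())
  # judge away from the reflection-padded edges
  core <- out$channels[[1]]$samples[(10 * fs):(110 * fs)]
  expect_lt(max(abs(core)), 10)
})

test_that("filtering an all-zero signal returns zeros of the same length", {
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = numeric(4000)),
         list(name = "EMG nuchal", role = "EMG", samples = numeric(4000))),
    fs = 400
  )
  out <- apply_acquisition_filters(rec, filter_spec())
  expect_equal(n_samples(out), 4000)
  expect_true(all(abs(out$channels[[1]]$samples) < 1e-10))
})

test_that("filtering is idempotent in the pass-band", {
  fs <- 400
  set.seed(5)
  # noise confined to 2-40 Hz, well inside the 0.3-70 Hz pass-band
  bp <- signal::butter(4, c(2, 40) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bp, stats::rnorm(60 * fs, sd = 20)))
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = x),
         list(name = "EMG nuchal", role = "EMG", samples = numeric(length(x)))),
    fs = fs)
  once <- apply_acquisition_filters(rec, filter_spec())
  twice <- apply_acquisition_filters(once, filter_spec())
  r1 <- sqrt(mean(once$channels[[1]]$samples^2))
  r2 <- sqrt(mean(twice$channels[[1]]$samples^2))
  expect_lt(abs(r2 - r1) / r1, 0.01)
})

test_that("a low sampling rate is rejected and adapt_filter_spec repairs it", {
  rec <- noise_recording(duration_s = 5, fs = 100)
  expect_error(apply_acquisition_filters(rec, filter_spec()), "too low")
  spec <- adapt_filter_spec(filter_spec(), 100)
  expect_equal(spec$eeg_lp_hz, 40)
  expect_true(is.na(spec$notch_hz))
  expect_silent(apply_acquisition_filters(rec, spec))
})

test_that("filter_spec validates corner ordering", {
  expect_error(filter_spec(eeg_hp_hz = 80, eeg_lp_hz = 70), "below")
  expect_error(filter_spec(notch_hz = 90), "inside the EEG pass-band")
})

test_that("artifact tagging flags large-amplitude epochs and keeps a shadow copy", {
  fs <- 100
  set.seed(7)
  n <- 60 * fs
  eeg <- stats::rnorm(n, sd = 10)
  m <- stats::mad(eeg)
  idx <- (20 * fs):(22 * fs)  # 2-s square pulse in epoch 3
  eeg[idx] <- 15 * m
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = eeg),
         list(name = "EMG nuchal", role = "EMG", samples = stats::rnorm(n))),
    fs = fs
  )
  hyp <- hypnogram(rep("SWS", 6))
  tagged <- tag_artifacts(rec, hyp)
  expect_equal(tagged$labels[3], "ARTIFACT")
  expect_equal(tagged$labels[-3], rep("SWS", 5))
  expect_equal(tagged$original, rep("SWS", 6))
})

test_that("clean epochs keep their labels and ARTIFACT is never reverted", {
  rec <- noise_recording(duration_s = 60, fs = 100, seed = 8)
  hyp <- hypnogram(c("ARTIFACT", rep("SWS", 5)))
  tagged <- tag_artifacts(rec, hyp)
  expect_equal(tagged$labels[1], "ARTIFACT")
  expect_equal(tagged$labels[-1], rep("SWS", 5))
})

test_that("a fully saturated recording makes the pipeline refuse to analyze", {
  fs <- 100
  n <- 120 * fs
  sq <- rep(c(600, -600), length.out = n) + stats::rnorm(n, sd = 1)
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = sq),
         list(name = "EMG nuchal", role = "EMG", samples = stats::rnorm(n))),
    fs = fs
  )
  hyp <- hypnogram(rep("SWS", 12))
  tagged <- tag_artifacts(rec, hyp, clip_limit = 500)
  expect_true(all(tagged$labels == "ARTIFACT"))
  expect_error(estimate_background(rec, tagged), "no background")
})
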