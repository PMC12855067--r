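# Event spectra: Welch estimator, normalization semantics, peak
# extraction accuracy, cohort summaries.

mk_rec <- function(eeg, fs = 100) {
  signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = eeg),
         list(name = "EMG nuchal", role = "EMG",
              samples = numeric(length(eeg)))),
    fs = fs)
}

test_that("Welch PSD satisfies a Parseval-style identity", {
  set.seed(61)
  x <- stats::rnorm(2000)
  p <- welch_psd(x, 100)
  df <- p$freq[2] - p$freq[1]
  expect_lt(abs(sum(p$psd) * df - stats::var(x)) / stats::var(x), 0.05)
})

test_that("the PSD of a pure sinusoid event peaks at its frequency", {
  fs <- 100
  t <- (0:(4 * fs - 1)) / fs
  rec <- mk_rec(c(numeric(fs), 50 * sin(2 * pi * 6.73 * t), numeric(fs)))
  ev <- list(onset_s = 1, offset_s = 5)
  p <- event_psd(rec, ev)
  expect_lt(abs(p$freq[which.max(p$psd)] - 6.73), 0.05)
})

test_that("white noise shows no spurious spectral line", {
  set.seed(62)
  nmax <- replicate(20, {
    p <- welch_psd(stats::rnorm(3000), 100)
    sel <- p$freq >= 1 & p$freq <= 30
    max(p$psd[sel]) / stats::median(p$psd[sel])
  })
  expect_lt(stats::median(nmax), 3)
})

test_that("zero and too-short segments behave as specified", {
  rec <- mk_rec(numeric(1000))
  p <- event_psd(rec, list(onset_s = 1, offset_s = 5))
  expect_true(all(p$psd == 0))
  expect_error(event_psd(rec, list(onset_s = 1, offset_s = 1.1)), "too short")
  expect_error(event_psd(rec, list(onset_s = 1, offset_s = 50)), "outside")
})

test_that("the reference PSD excludes artifact epochs", {
  set.seed(63)
  fs <- 100
  eeg <- stats::rnorm(60 * fs, sd = 20)
  eeg[(20 * fs):(21 * fs)] <- 2000  # huge transient inside epoch 3
  rec <- mk_rec(eeg)
  hyp <- hypnogram(c("SWS", "SWS", "ARTIFACT", rep("SWS", 3)))
  ref <- reference_psd(rec, hyp)
  clean <- reference_psd(mk_rec(stats::rnorm(60 * fs, sd = 20)),
                         hypnogram(rep("SWS", 6)))
  sel <- ref$freq >= 1 & ref$freq <= 30
  expect_lt(abs(sum(ref$psd[sel]) / sum(clean$psd[sel]) - 1), 0.25)
  expect_error(reference_psd(rec, hypnogram(rep("ARTIFACT", 6))),
               "no artifact-free")
})

test_that("normalization is ratio-first then percent-of-total", {
  grid_psd <- function(vals) list(freq = seq(0.5, 30, 0.1), psd = vals)
  n <- length(seq(0.5, 30, 0.1))
  flat <- normalize_spectrum(grid_psd(rep(2, n)), grid_psd(rep(2, n)))
  expect_equal(sum(flat$power_pct), 100, tolerance = 1e-9)
  expect_equal(flat$power_pct, rep(100 / n, n), tolerance = 1e-9)

  ev <- rep(2, n); ev[100] <- 20
  one <- normalize_spectrum(grid_psd(ev), grid_psd(rep(2, n)))
  expect_equal(one$power_pct[100] / (100 / (n + 9)), 10, tolerance = 0.01)

  ref0 <- rep(2, n); ref0[5] <- 0
  fl <- normalize_spectrum(grid_psd(ev), grid_psd(ref0))
  expect_true(all(is.finite(fl$power_pct)))
})

test_that("normalized spectra are invariant under amplitude scaling", {
  set.seed(64)
  fs <- 100
  t <- (0:(60 * fs - 1)) / fs
  eeg <- stats::rnorm(length(t), sd = 20)
  idx <- (30 * fs):(32 * fs)
  eeg[idx] <- eeg[idx] + 80 * sin(2 * pi * 6.73 * (idx - idx[1]) / fs)
  hyp <- hypnogram(rep("SWS", 6))
  ev <- list(onset_s = 30, offset_s = 32)
  s1 <- normalize_spectrum(event_psd(mk_rec(eeg), ev),
                           reference_psd(mk_rec(eeg), hyp))
  s2 <- normalize_spectrum(event_psd(mk_rec(eeg * 7), ev),
                           reference_psd(mk_rec(eeg * 7), hyp))
  expect_equal(s1$power_pct, s2$power_pct, tolerance = 1e-9)
})

test_that("peak extraction recovers a two-component event to sub-bin accuracy", {
  fs <- 100
  t <- (0:(2 * fs - 1)) / fs
  wave <- sin(2 * pi * 6.73 * t) + 0.45 * sin(2 * pi * 13.28 * t)
  set.seed(65)
  eeg <- c(stats::rnorm(30 * fs, sd = 1), 60 * wave, stats::rnorm(30 * fs, sd = 1))
  rec <- mk_rec(eeg)
  hyp <- hypnogram(rep("SWS", floor(length(eeg) / fs / 10)))
  sp <- extract_peaks(normalize_spectrum(
    event_psd(rec, list(onset_s = 30, offset_s = 32)),
    reference_psd(rec, hyp)))
  expect_lt(abs(sp$peak1_hz - 6.73), 0.15)
  expect_lt(abs(sp$peak2_hz - 13.28), 0.15)
})

test_that("noiseless sinusoids are located to within 0.05 Hz", {
  fs <- 100
  for (f0 in c(5.37, 6.73, 9.11)) {
    t <- (0:(3 * fs - 1)) / fs
    rec <- mk_rec(50 * sin(2 * pi * f0 * t))
    p <- event_psd(rec, list(onset_s = 0, offset_s = 3))
    sp <- extract_peaks(list(freq = p$freq, power_pct = p$psd))
    expect_lt(abs(sp$peak1_hz - f0), 0.05)
  }
})

test_that("single-line and flat spectra flag missing peaks", {
  fs <- 100
  t <- (0:(2 * fs - 1)) / fs
  p <- event_psd(mk_rec(40 * sin(2 * pi * 7 * t)), list(onset_s = 0, offset_s = 2))
  sp <- extract_peaks(list(freq = p$freq, power_pct = p$psd))
  expect_lt(abs(sp$peak1_hz - 7), 0.1)
  expect_true(is.na(sp$peak2_hz))

  n <- length(seq(0.5, 30, 0.1))
  flat <- extract_peaks(list(freq = seq(0.5, 30, 0.1), power_pct = rep(1, n)))
  expect_true(is.na(flat$peak1_hz))
  expect_true(is.na(flat$peak2_hz))
})

test_that("cohort summary pools per-mouse means and flags empty mice", {
  spec <- list(freq = seq(0.5, 30, 0.1),
               power_pct = rep(1, 296), peak1_hz = 6.7, peak2_hz = 13.3)
  out <- suppressWarnings(
    cohort_peak_summary(list(m1 = list(spec), m2 = list(spec), m3 = list()))
  )
  expect_equal(nrow(out$per_mouse), 2L)
  expect_equal(out$population$peak1_sem, 0)
  expect_equal(out$population$peak1_mean, 6.7)
  expect_warning(cohort_peak_summary(list(m = list())), "no usable events")
})
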