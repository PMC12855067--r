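# Synthetic-data generator: hypnogram chain, event placement, calibrated
# statistical structure, determinism.

test_that("identity transition matrices freeze the chain in its initial state", {
  P <- diag(3)
  dimnames(P) <- list(c("WAKE", "SWS", "REM"), c("WAKE", "SWS", "REM"))
  m <- hypnogram_model(P_on = P, P_off = P)
  hyp <- simulate_hypnogram(m, duration_h = 2, seed = 1)
  expect_equal(length(unique(hyp$labels)), 1L)
})

test_that("non-stochastic and WAKE->REM matrices are rejected", {
  P <- matrix(c(0.9, 0.1, 0, 0.1, 0.9, 0, 0.1, 0.1, 0.8), 3, byrow = TRUE,
              dimnames = list(c("WAKE", "SWS", "REM"), c("WAKE", "SWS", "REM")))
  bad <- P; bad[1, ] <- c(0.5, 0.4, 0.2)
  expect_error(hypnogram_model(P_on = bad, P_off = P), "row-stochastic")
  bad2 <- P; bad2[1, ] <- c(0.8, 0.1, 0.1)
  expect_error(hypnogram_model(P_on = bad2, P_off = P), "WAKE->REM")
})

test_that("the default chain realizes ~50% SWS and ~5% REM with sleep in lights-on", {
  sws <- rem <- sws_on <- sws_off <- numeric(20)
  for (s in 1:20) {
    hyp <- simulate_hypnogram(duration_h = 24, seed = s)
    lab <- hyp$labels
    sws[s] <- mean(lab == "SWS")
    rem[s] <- mean(lab == "REM")
    on <- epoch_zt(hyp) < 12
    sws_on[s] <- mean(lab[on] %in% c("SWS", "REM"))
    sws_off[s] <- mean(lab[!on] %in% c("SWS", "REM"))
  }
  expect_lt(abs(mean(sws) - 0.50), 0.05)
  expect_lt(abs(mean(rem) - 0.05), 0.02)
  expect_gt(mean(sws_on), mean(sws_off))  # sleep concentrated lights-on
})

test_that("profiles scale event intensity and unknown names are rejected", {
  expect_error(strain_profile("nzo_like"), "known profiles")
  jax <- strain_profile("jax_like")
  ola <- strain_profile("ola_like")
  expect_equal(unname(ola$state_rates / jax$state_rates),
               rep(1.5 / 93, 3))
  none <- strain_profile("c57_like")
  day <- simulate_day(none, duration_h = 24, seed = 1)
  expect_equal(nrow(day$events), 0L)
})

test_that("ground-truth daily counts and state shares match the calibration", {
  counts <- 0; by_state <- c(SWS = 0, WAKE = 0, REM = 0)
  hours <- c(SWS = 0, WAKE = 0, REM = 0)
  for (s in 1:12) {
    day <- simulate_day(strain_profile("jax_like"), duration_h = 24, seed = s)
    counts <- counts + nrow(day$events)
    tb <- table(factor(day$events$state, levels = names(by_state)))
    by_state <- by_state + as.numeric(tb)
    for (st in names(hours)) hours[st] <- hours[st] + hours_in_state(day$hypnogram, st)
  }
  expect_lt(abs(counts / 12 - 93), 93 * 0.15)
  shares <- 100 * by_state / sum(by_state)
  expect_gt(shares[["SWS"]], 90)
  expect_lt(shares[["WAKE"]], 8)
  # shares converge to lambda_s T_s / sum over the realized hypnogram
  lam <- strain_profile("jax_like")$state_rates[names(hours)]
  pred <- 100 * lam * hours / sum(lam * hours)
  expect_lt(max(abs(shares - pred)), 3)
})

test_that("realized hourly intensity tracks the circadian modulation", {
  cnt <- numeric(24)
  sws_h <- numeric(24)
  for (s in 1:25) {
    day <- simulate_day(strain_profile("jax_like"), duration_h = 24, seed = 100 + s)
    zt <- floor(day$events$onset_zt_h)
    cnt <- cnt + tabulate(zt + 1, 24)
  }
  expect_gt(stats::cor(cnt, circadian_modulation((0:23) + 0.5)), 0.8)
})

test_that("event durations satisfy the 4-cycle floor and ~2 s mean", {
  day <- simulate_day(strain_profile("jax_like", daily_event_mean = 2000),
                      duration_h = 24, seed = 3)
  d <- event_durations(day$events)
  expect_true(all(d >= 4 / 6.73 - 1e-9))
  expect_true(all(d <= 6 + 1e-9))
  expect_lt(abs(mean(d) - 2), 0.15)
})

test_that("no two ground-truth events overlap", {
  day <- simulate_day(strain_profile("jax_like", daily_event_mean = 1500),
                      duration_h = 24, seed = 4)
  ev <- day$events
  expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
})

test_that("a zero-event profile injects no waveform energy at the fundamental", {
  sim <- simulate_recording(strain_profile("c57_like"), duration_h = 0.5,
                            fs = 100, seed = 5)
  expect_equal(nrow(sim$events), 0L)
  p <- welch_psd(get_channel(sim$recording, "EEG")$samples, 100)
  # no line at the fundamental: compare with the immediate spectral
  # neighborhood (the background PSD is far from flat across 3-20 Hz)
  at_f0 <- mean(p$psd[abs(p$freq - 6.73) < 0.2])
  nearby <- mean(p$psd[abs(p$freq - 6.73) > 0.5 & abs(p$freq - 6.73) < 1.5])
  expect_lt(at_f0, 1.5 * nearby)
})

test_that("fixture export is deterministic in seed and profile", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  p1 <- export_fixture(d1, "jax_like", seed = 11, duration_h = 0.5)
  p2 <- export_fixture(d2, "jax_like", seed = 11, duration_h = 0.5)
  expect_identical(readLines(p1[["events"]]), readLines(p2[["events"]]))
  expect_identical(readLines(p1[["hypnogram"]]), readLines(p2[["hypnogram"]]))
  expect_identical(readBin(p1[["edf"]], "raw", file.size(p1[["edf"]])),
                   readBin(p2[["edf"]], "raw", file.size(p2[["edf"]])))
  p3 <- export_fixture(d1, "jax_like", seed = 12, duration_h = 0.5)
  expect_false(identical(readLines(p1[["events"]]), readLines(p3[["events"]])))
})

test_that("profiles round-trip through YAML", {
  path <- system.file("extdata", "profiles", "ola_like.yaml",
                      package = "somnispike")
  prof <- read_profile(path)
  expect_s3_class(prof, "strain_profile")
  expect_equal(prof$daily_event_mean, 1.5)
  expect_equal(prof$awakening_hazard, 3)
})

test_that("invalid durations are rejected", {
  expect_error(simulate_day(duration_h = 0), "positive")
  expect_error(simulate_hypnogram(duration_h = -1), "positive")
})
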