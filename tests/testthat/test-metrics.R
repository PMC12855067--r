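# Sleep architecture and SWD-sleep interaction statistics.

test_that("architecture metrics match hand enumeration", {
  hyp <- hypnogram(c("WAKE", "WAKE", "SWS", "SWS", "SWS", "REM", "WAKE"))
  a <- summarize_architecture(hyp)
  expect_equal(unname(a$state_fraction), c(3, 3, 1) / 7)
  expect_equal(a$n_transitions, 3L)
  expect_equal(unname(a$bout_count), c(2, 1, 1))
  expect_equal(unname(a$bout_mean_s), c(15, 30, 10))
  expect_equal(unname(a$pair_freq[c("WAKE->SWS", "SWS->REM", "REM->WAKE")]),
               rep(1 / 3, 3))
  expect_equal(sum(a$pair_freq), 1)
})

test_that("degenerate hypnograms: constant, alternating, too short", {
  const <- summarize_architecture(hypnogram(rep("SWS", 100)))
  expect_equal(const$n_transitions, 0L)
  expect_equal(unname(const$bout_count[["SWS"]]), 1)

  alt <- summarize_architecture(hypnogram(rep(c("WAKE", "SWS"), 50)))
  expect_equal(alt$n_transitions, 99L)
  expect_equal(unname(alt$bout_mean_s[["WAKE"]]), 10)

  expect_error(summarize_architecture(hypnogram(c("SWS", "ARTIFACT"))),
               "fewer than 2")
})

test_that("ARTIFACT epochs break runs without creating transitions", {
  a <- summarize_architecture(hypnogram(c("WAKE", "ARTIFACT", "WAKE")))
  expect_equal(a$n_transitions, 0L)
  expect_equal(unname(a$bout_count[["WAKE"]]), 2)
  b <- summarize_architecture(hypnogram(c("WAKE", "ARTIFACT", "SWS")))
  expect_equal(b$n_transitions, 0L)
})

test_that("event attribution follows the onset-epoch rule", {
  hyp <- hypnogram(c(rep("SWS", 3), "WAKE", "WAKE"))  # SWS 0-30 s
  ev <- event_table(c(5, 29.8), c(7, 31.5), channel = "ch",
                    provenance = "ground_truth")
  att <- attribute_events(ev, hyp)
  expect_equal(att$events$state, c("SWS", "SWS"))  # onset before boundary
  expect_equal(unname(att$state_counts[["SWS"]]), 2)
  expect_equal(unname(att$state_shares_pct[["SWS"]]), 100)
  # 3 epochs of SWS = 1/120 h -> rate = 2 / (30/3600)
  expect_equal(unname(att$rate_per_h[["SWS"]]), 2 / (30 / 3600))
})

test_that("events in ARTIFACT epochs are excluded from shares", {
  hyp <- hypnogram(c("SWS", "ARTIFACT", "SWS"))
  ev <- event_table(c(2, 12), c(4, 14), channel = "ch",
                    provenance = "ground_truth")
  att <- attribute_events(ev, hyp)
  expect_equal(att$n_artifact_events, 1L)
  expect_equal(sum(att$state_counts), 1)
})

test_that("conditional transition probabilities match a hand case", {
  hyp <- hypnogram(c("SWS", "SWS", "SWS", "WAKE"))
  ev <- event_table(21, 23, channel = "ch", provenance = "ground_truth")
  ct <- conditional_transitions(ev, hyp, n_boot = 0)
  expect_equal(ct$p_transition_swd, 1)
  expect_equal(ct$p_transition_free, 0)
  expect_true(is.na(ct$ratio))  # undefined when the clean rate is zero
  expect_equal(ct$n_swd_epochs, 1L)
  expect_equal(unname(ct$pair_prob_swd[["SWS->WAKE"]]), 1)
})

test_that("any-overlap containment marks every epoch an event touches", {
  hyp <- hypnogram(rep("SWS", 4))
  ev <- event_table(9, 21, channel = "ch", provenance = "ground_truth")
  ct <- conditional_transitions(ev, hyp, n_boot = 0)
  expect_equal(ct$n_swd_epochs, 3L)  # epochs 1-3
  ct2 <- conditional_transitions(ev, hyp, containment = "onset", n_boot = 0)
  expect_equal(ct2$n_swd_epochs, 1L)
})

test_that("random event placement gives a unit transition ratio", {
  set.seed(77)
  hyp <- simulate_hypnogram(duration_h = 24, seed = 7)
  n <- n_epochs(hyp)
  ratios <- replicate(200, {
    ep <- sample.int(n - 1L, 90)
    ev <- event_table(sort((ep - 1) * 10 + 2), sort((ep - 1) * 10 + 2) + 1,
                      channel = "ch", provenance = "ground_truth")
    conditional_transitions(ev, hyp, n_boot = 0)$ratio
  })
  expect_lt(abs(mean(ratios, na.rm = TRUE) - 1), 0.05)
})

test_that("fragmentation correlation handles exact and degenerate input", {
  col <- correlate_fragmentation(c(2, 4, 6), c(1, 2, 3))
  expect_equal(col$r, 1)
  anti <- correlate_fragmentation(c(6, 4, 2), c(1, 2, 3))
  expect_equal(anti$r, -1)
  flat <- correlate_fragmentation(c(5, 5, 5), c(1, 2, 3))
  expect_true(flat$degenerate)
  expect_error(correlate_fragmentation(1:2, 1:2), "at least 3")
})

test_that("severely affected animals have more fragmented sleep (coupling)", {
  # per-event the awakening hazard adds only ~0.06 expected transitions,
  # so the correlation needs a cohort spanning a wide severity range to
  # rise above the chain's own between-day variability
  set.seed(88)
  m <- rep(seq(20, 600, length.out = 12), 3)
  trans <- swd <- numeric(length(m))
  for (i in seq_along(m)) {
    day <- simulate_day(strain_profile("jax_like", daily_event_mean = m[i]),
                        duration_h = 24)
    trans[i] <- summarize_architecture(day$hypnogram)$n_transitions
    swd[i] <- nrow(day$events)
  }
  res <- correlate_fragmentation(trans, swd)
  expect_gt(res$r, 0)
  expect_lt(res$p, 0.05)
})
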