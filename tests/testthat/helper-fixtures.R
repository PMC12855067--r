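# Shared fixtures. Heavy simulations are computed once per test run and
# cached in this environment so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small two-channel recording of white noise (for I/O and filter tests)
noise_recording <- function(duration_s = 60, fs = 400, seed = 1, sd = 20) {
  set.seed(seed)
  n <- duration_s * fs
  signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal",
              samples = stats::rnorm(n, sd = sd)),
         list(name = "EMG nuchal", role = "EMG",
              samples = stats::rnorm(n, sd = sd))),
    fs = fs
  )
}

# recording with white-noise EEG and injected sinusoidal bursts; returns
# the recording, an all-WAKE hypnogram, and the injected intervals
burst_recording <- function(duration_s = 300, fs = 100, seed = 2,
                            bursts = list(), noise_sd = 20) {
  set.seed(seed)
  n <- duration_s * fs
  eeg <- stats::rnorm(n, sd = noise_sd)
  for (b in bursts) {
    idx <- (round(b$onset_s * fs) + 1L):round(b$offset_s * fs)
    tau <- (seq_along(idx) - 1L) / fs
    w <- b$amp * sin(2 * pi * b$freq * tau)
    if (!is.null(b$amp2)) w <- w + b$amp2 * sin(2 * pi * b$freq2 * tau)
    taper <- if (is.null(b$taper)) 0.1 else b$taper
    env <- somnispike:::raised_cosine_env(length(idx), fs, taper)
    eeg[idx] <- eeg[idx] + w * env
  }
  rec <- signal_recording(
    list(list(name = "EEG frontal", role = "EEG_frontal", samples = eeg),
         list(name = "EMG nuchal", role = "EMG",
              samples = stats::rnorm(n, sd = 5))),
    fs = fs
  )
  hyp <- hypnogram(rep("WAKE", floor(duration_s / 10)))
  list(rec = rec, hyp = hyp)
}

# the affected-strain acceptance cohort (8 animals, 24 h, seeds 1-8),
# analyzed end to end; shared by several acceptance criteria
jax_cohort <- function() {
  cached("jax_cohort", run_cohort("jax_like", seeds = 1:8))
}

# a second detection arm (seeds 9-16, spectra skipped) pooled with the
# cohort for the circadian rate ratio, whose per-bin counts are Poisson
# noisy at 8 days
jax_arm2 <- function() {
  cached("jax_arm2", lapply(9:16, function(s)
    run_animal("jax_like", seed = s, spectra = FALSE)))
}
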