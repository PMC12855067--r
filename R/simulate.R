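# Synthetic 24-h EEG/EMG generator with ground truth. The generator is
# phenomenological: an inhomogeneous (light/dark) Markov chain over
# WAKE/SWS/REM at 10-s resolution, state-conditional Poisson placement of
# spike-and-wave discharges with multiplicative circadian intensity and a
# next-epoch awakening hazard, state-dependent background EEG/EMG noise,
# and two-component sinusoidal discharge waveforms.

#' Strain profile for the discharge generator
#'
#' Built-in profiles: `"jax_like"` (affected: ~93 discharges/24 h),
#' `"ola_like"` (~1.5/24 h), `"c57_like"` (none). State-conditional
#' intensities are per hour spent in each state and are scaled from the
#' affected calibration (7.3/h SWS, 0.43/h WAKE, 0.77/h REM, which under
#' the default hypnogram composition yields ~94%/5%/1% state shares and
#' ~93 events/day). The circadian modulation is
#' `c(t) = exp(beta * cos(2*pi*(t - acrophase)/24)) / I0(beta)`
#' (daily mean 1); `beta = 1.24` makes the SWS-rate ratio between ZT11-12
#' and ZT5-6 approximately 4. `awakening_hazard` multiplies P(SWS->WAKE)
#' in the epoch following an SWD-containing SWS epoch (row renormalized).
#'
#' @param name profile name, or a list of fields to override.
#' @param ... field overrides (e.g. `daily_event_mean`).
#' @return object of class `strain_profile`.
#' @export
strain_profile <- function(name = "jax_like", ...) {
  base <- list(
    name = "jax_like",
    daily_event_mean = 93,
    state_rates = c(SWS = 7.3, WAKE = 0.43, REM = 0.77),
    circadian_beta = 1.24,
    acrophase_h = 12,
    awakening_hazard = 3
  )
  known <- list(
    jax_like = list(daily_event_mean = 93),
    ola_like = list(daily_event_mean = 1.5),
    c57_like = list(daily_event_mean = 0)
  )
  if (is.list(name)) {
    fields <- utils::modifyList(base, name)
  } else {
    if (!name %in% names(known)) {
      stop("unknown profile '", name, "'; known profiles: ",
           paste(names(known), collapse = ", "))
    }
    fields <- utils::modifyList(base, c(list(name = name), known[[name]]))
  }
  fields <- utils::modifyList(fields, list(...))
  # intensities scale with the daily mean; shares stay 94/5/1
  fields$state_rates <- base$state_rates * fields$daily_event_mean / 93
  if (any(fields$state_rates < 0) || fields$awakening_hazard < 1) {
    stop("rates must be >= 0 and awakening_hazard >= 1")
  }
  structure(fields, class = "strain_profile")
}

#' Read a strain profile from YAML
#' @param path YAML file with profile fields.
#' @export
read_profile <- function(path) {
  strain_profile(yaml::read_yaml(path))
}

#' Circadian intensity modulation
#'
#' Exponentiated-cosine intensity, strictly positive and normalized so the
#' daily mean is 1.
#' @param t_h ZT hours.
#' @param beta modulation depth.
#' @param acrophase_h ZT of peak intensity.
#' @export
circadian_modulation <- function(t_h, beta = 1.24, acrophase_h = 12) {
  exp(beta * cos(2 * pi * (t_h - acrophase_h) / 24)) / besselI(beta, 0)
}

#' Spike-and-wave discharge waveform specification
#'
#' Each discharge is a two-component sum of sinusoids (fundamental `f0_hz`
#' and a second, independently set component `f1_hz`; the measured second
#' spectral peak of these discharges is not an exact harmonic) under a
#' raised-cosine onset/offset envelope, with log-normal duration
#' (arithmetic mean `dur_mean_s`, log-SD `dur_sdlog`) truncated to
#' `[4/f0_hz, dur_max_s]` so the 4-cycle detection criterion is
#' satisfiable by construction. Amplitude is `k` times the RMS of the
#' surrounding state's background EEG.
#'
#' @param f0_hz fundamental frequency (Hz).
#' @param f1_hz second component frequency (Hz).
#' @param amp_ratio amplitude of the second component relative to the
#'   fundamental.
#' @param phase relative phase of the second component (radians).
#' @param dur_mean_s,dur_sdlog,dur_max_s duration distribution.
#' @param k amplitude scale in units of background RMS.
#' @param taper_s raised-cosine ramp length (s) at onset and offset.
#' @export
swd_waveform_spec <- function(f0_hz = 6.73, f1_hz = 13.28, amp_ratio = 0.45,
                              phase = 0, dur_mean_s = 2.0, dur_sdlog = 0.25,
                              dur_max_s = 6.0, k = 2.5, taper_s = 0.1) {
  structure(list(f0_hz = f0_hz, f1_hz = f1_hz, amp_ratio = amp_ratio,
                 phase = phase, dur_mean_s = dur_mean_s,
                 dur_sdlog = dur_sdlog, dur_min_s = 4 / f0_hz,
                 dur_max_s = dur_max_s, k = k, taper_s = taper_s),
            class = "swd_waveform_spec")
}

#' Vigilance-state transition model
#'
#' Two 3x3 epoch-transition matrices (lights-on and lights-off) over
#' WAKE/SWS/REM. The defaults are calibrated so the realized 24-h
#' composition is ~50% SWS and ~5% REM with sleep concentrated in
#' lights-on, REM reachable only from SWS, and a polyphasic bout structure
#' (several hundred transitions per day).
#'
#' @param P_on,P_off row-stochastic 3x3 matrices (rows/cols
#'   WAKE, SWS, REM).
#' @export
hypnogram_model <- function(P_on = NULL, P_off = NULL) {
  st <- c("WAKE", "SWS", "REM")
  if (is.null(P_on)) {
    P_on <- matrix(c(0.89359, 0.10641, 0,
                     0.05198, 0.94444, 0.00358,
                     0.03000, 0.00333, 0.96667),
                   nrow = 3, byrow = TRUE, dimnames = list(st, st))
  }
  if (is.null(P_off)) {
    P_off <- matrix(c(0.94970, 0.05030, 0,
                      0.07450, 0.92308, 0.00242,
                      0.03000, 0.00333, 0.96667),
                    nrow = 3, byrow = TRUE, dimnames = list(st, st))
  }
  for (P in list(P_on, P_off)) {
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-6)) {
      stop("transition matrices must be row-stochastic")
    }
    if (P["WAKE", "REM"] > 0) stop("direct WAKE->REM transitions are not allowed")
  }
  structure(list(P_on = P_on, P_off = P_off), class = "hypnogram_model")
}

#' Simulate a hypnogram
#'
#' Draws an epoch sequence from the light-phase-dependent Markov chain.
#'
#' @param model a `hypnogram_model`.
#' @param duration_h recording length in hours.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param epoch_len_s epoch length (s).
#' @param start_zt ZT of the first epoch.
#' @param light_period_h lights-on duration (h).
#' @return a `hypnogram`.
#' @export
simulate_hypnogram <- function(model = hypnogram_model(), duration_h = 24,
                               seed = NULL, epoch_len_s = 10, start_zt = 0,
                               light_period_h = 12) {
  if (duration_h <= 0) stop("duration_h must be positive")
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_day(profile = strain_profile("c57_like"), model = model,
                      duration_h = duration_h, seed = NULL,
                      epoch_len_s = epoch_len_s, start_zt = start_zt,
                      light_period_h = light_period_h)
  sim$hypnogram
}

# stationary distribution of a stochastic matrix (initial-state draw)
chain_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Co-simulate vigilance states and ground-truth discharge events
#'
#' Epoch by epoch: (1) the next state is drawn from the phase-appropriate
#' matrix, with P(SWS->WAKE) multiplied by the awakening hazard (row
#' renormalized) iff the previous epoch contained at least one discharge;
#' (2) given the state and the epoch-midpoint ZT, a Poisson count of
#' discharges is drawn at the state intensity times the circadian
#' modulation, and events are placed uniformly within the epoch without
#' overlap (an event may spill into the next epoch; its attributed state
#' is its onset state).
#'
#' @inheritParams simulate_hypnogram
#' @param profile a `strain_profile`.
#' @param waveform a `swd_waveform_spec` (durations are drawn here).
#' @return list with `hypnogram` and `events` (ground truth).
#' @export
simulate_day <- function(profile = strain_profile(), model = hypnogram_model(),
                         waveform = swd_waveform_spec(), duration_h = 24,
                         seed = NULL, epoch_len_s = 10, start_zt = 0,
                         light_period_h = 12) {
  if (duration_h <= 0) stop("duration_h must be positive")
  if (!is.null(seed)) set.seed(seed)
  st <- c("WAKE", "SWS", "REM")
  n_ep <- floor(duration_h * 3600 / epoch_len_s)
  zt0 <- zt_at((seq_len(n_ep) - 1L) * epoch_len_s, start_zt)
  lights_on <- (zt0 %% 24) < light_period_h
  zt_mid <- zt_at((seq_len(n_ep) - 0.5) * epoch_len_s, start_zt)
  cmod <- circadian_modulation(zt_mid, profile$circadian_beta,
                               profile$acrophase_h)
  lam_epoch <- profile$state_rates * epoch_len_s / 3600  # per-epoch means

  labels <- character(n_ep)
  ev_on <- ev_off <- numeric(0)
  ev_state <- character(0)
  prev_had_swd <- FALSE
  prev_spill_end <- -Inf
  state <- sample(st, 1, prob = chain_stationary(
    if (lights_on[1L]) model$P_on else model$P_off))
  for (e in seq_len(n_ep)) {
    if (e > 1L) {
      P <- if (lights_on[e]) model$P_on else model$P_off
      p <- P[state, ]
      if (prev_had_swd && state == "SWS" && profile$awakening_hazard != 1) {
        p["WAKE"] <- p["WAKE"] * profile$awakening_hazard
        p <- p / sum(p)
      }
      state <- sample(st, 1, prob = p)
    }
    labels[e] <- state
    m <- stats::rpois(1, lam_epoch[[state]] * cmod[e])
    prev_had_swd <- m > 0L
    if (m > 0L) {
      t0 <- (e - 1L) * epoch_len_s
      dur <- draw_durations(m, waveform)
      placed <- place_events(m, dur, epoch_len_s, max(0, prev_spill_end - t0))
      if (length(placed$onset) > 0L) {
        ev_on <- c(ev_on, t0 + placed$onset)
        ev_off <- c(ev_off, t0 + placed$offset)
        ev_state <- c(ev_state, rep(state, length(placed$onset)))
        prev_spill_end <- max(prev_spill_end, t0 + max(placed$offset))
      }
      prev_had_swd <- length(placed$onset) > 0L
    }
  }
  dur_total <- n_ep * epoch_len_s
  keep <- ev_off <= dur_total
  events <- event_table(ev_on[keep], ev_off[keep], channel = "EEG frontal",
                        state = ev_state[keep],
                        onset_zt_h = zt_at(ev_on[keep], start_zt),
                        provenance = "ground_truth")
  list(hypnogram = hypnogram(labels, epoch_len_s = epoch_len_s,
                             start_zt = start_zt),
       events = events)
}

draw_durations <- function(m, waveform) {
  mu <- log(waveform$dur_mean_s) - waveform$dur_sdlog^2 / 2
  d <- stats::rlnorm(m, mu, waveform$dur_sdlog)
  pmin(pmax(d, waveform$dur_min_s), waveform$dur_max_s)
}

# place m events of durations dur uniformly in [avoid_until, epoch_len),
# rejecting overlapping configurations; drops events if no fit found
place_events <- function(m, dur, epoch_len_s, avoid_until = 0) {
  for (attempt in 1:50) {
    onset <- sort(stats::runif(m, avoid_until, epoch_len_s))
    offset <- onset + dur
    if (m == 1L || all(onset[-1L] >= offset[-m])) {
      return(list(onset = onset, offset = offset))
    }
  }
  # fall back to the first event only (vanishingly rare at realistic rates)
  list(onset = onset[1L], offset = offset[1L])
}

# per-state background mixing weights (uV RMS) over the three noise
# streams (delta-band, theta-band, broadband) and EMG tone
STATE_MIX <- rbind(
  WAKE = c(delta = 8, theta = 10, broad = 12),
  SWS = c(delta = 40, theta = 8, broad = 10),
  REM = c(delta = 5, theta = 25, broad = 8),
  ARTIFACT = c(delta = 8, theta = 10, broad = 12)
)
STATE_EMG_RMS <- c(WAKE = 30, SWS = 8, REM = 3, ARTIFACT = 30)
STATE_EEG_RMS <- sqrt(rowSums(STATE_MIX^2))

#' Synthesize EEG/EMG signals for a hypnogram and event list
#'
#' Background EEG is a per-state mixture of three filtered-noise streams
#' (delta-emphasized high-amplitude for SWS, low-amplitude broadband for
#' WAKE, theta-dominant for REM); EMG is high-passed noise with
#' state-dependent variance (high WAKE, low SWS, minimal REM). Each
#' discharge adds `A1*sin(2*pi*f0*tau) + A2*sin(2*pi*f1*tau + phase)`
#' under its raised-cosine envelope, with `A1 = k *` the surrounding
#' state's background RMS.
#'
#' @param hyp hypnogram (defines per-epoch state).
#' @param events ground-truth `event_table`.
#' @param waveform a `swd_waveform_spec`.
#' @param fs sampling rate in Hz (>= 100).
#' @param seed integer seed or `NULL`.
#' @param mains_hz optional mains frequency to inject (default none).
#' @param emg_channel include the EMG channel (skipping it leaves the EEG
#'   and the RNG stream up to that point unchanged).
#' @return a `signal_recording` (channels "EEG frontal", "EMG nuchal").
#' @export
synthesize_signals <- function(hyp, events, waveform = swd_waveform_spec(),
                               fs = 100, seed = NULL, mains_hz = NULL,
                               emg_channel = TRUE) {
  if (fs < 100) stop("fs must be at least 100 Hz")
  if (!is.null(seed)) set.seed(seed)
  n_ep <- n_epochs(hyp)
  ep_n <- round(hyp$epoch_len_s * fs)
  n <- n_ep * ep_n

  streams <- cbind(
    delta = filtered_noise(n, fs, c(NA, 4)),
    theta = filtered_noise(n, fs, c(5, 9)),
    broad = filtered_noise(n, fs, c(NA, 30))
  )
  w <- STATE_MIX[hyp$labels, , drop = FALSE]
  widx <- rep(seq_len(n_ep), each = ep_n)
  eeg <- streams[, 1] * w[widx, 1] + streams[, 2] * w[widx, 2] +
         streams[, 3] * w[widx, 3]
  emg <- if (emg_channel) {
    hp <- signal::butter(4, 10 / (fs / 2), type = "high")
    e <- spectral_noise(n, fs, function(fr) filter_mag_sq(hp$b, hp$a, fr, fs),
                        cache_key = "emg_hp10")
    e / stats::sd(e) * STATE_EMG_RMS[hyp$labels][widx]
  } else NULL

  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      i0 <- floor(events$onset_s[i] * fs) + 1L
      i1 <- min(n, ceiling(events$offset_s[i] * fs))
      if (i0 > n) next
      tau <- (seq(i0, i1) - i0) / fs
      a1 <- waveform$k * STATE_EEG_RMS[[events$state[i]]]
      wavef <- a1 * sin(2 * pi * waveform$f0_hz * tau) +
        a1 * waveform$amp_ratio * sin(2 * pi * waveform$f1_hz * tau +
                                        waveform$phase)
      eeg[i0:i1] <- eeg[i0:i1] + wavef * raised_cosine_env(length(tau), fs,
                                                           waveform$taper_s)
    }
  }
  if (!is.null(mains_hz)) {
    line <- 5 * sin(2 * pi * mains_hz * (seq_len(n) - 1L) / fs)
    eeg <- eeg + line
    if (!is.null(emg)) emg <- emg + line
  }
  channels <- list(list(name = "EEG frontal", role = "EEG_frontal",
                        samples = eeg))
  if (!is.null(emg)) {
    channels <- c(channels, list(list(name = "EMG nuchal", role = "EMG",
                                      samples = emg)))
  }
  signal_recording(channels, fs = fs, start_zt = hyp$start_zt)
}

filtered_noise <- function(n, fs, band) {
  f <- if (is.na(band[1])) {
    signal::butter(2, band[2] / (fs / 2), type = "low")
  } else {
    signal::butter(2, band / (fs / 2), type = "pass")
  }
  y <- spectral_noise(n, fs, function(fr) filter_mag_sq(f$b, f$a, fr, fs),
                      cache_key = paste0("noise", band[1], "-", band[2]))
  y / stats::sd(y)
}

raised_cosine_env <- function(n, fs, taper_s) {
  env <- rep(1, n)
  k <- min(n %/% 2L, round(taper_s * fs))
  if (k > 0L) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(k) - 0.5) / k)
    env[seq_len(k)] <- ramp
    env[n + 1L - seq_len(k)] <- ramp
  }
  env
}

#' Simulate a full recording with ground truth
#'
#' Runs `simulate_day()` and `synthesize_signals()` under a single seeded
#' RNG stream, so results are bit-reproducible given
#' `(profile, seed, version)`.
#'
#' @inheritParams simulate_day
#' @inheritParams synthesize_signals
#' @return list with `recording`, `hypnogram`, `events`.
#' @export
simulate_recording <- function(profile = strain_profile(),
                               model = hypnogram_model(),
                               waveform = swd_waveform_spec(),
                               duration_h = 24, fs = 100, seed = 1,
                               start_zt = 0, light_period_h = 12,
                               mains_hz = NULL, emg_channel = TRUE) {
  set.seed(seed)
  day <- simulate_day(profile, model, waveform, duration_h, seed = NULL,
                      start_zt = start_zt, light_period_h = light_period_h)
  rec <- synthesize_signals(day$hypnogram, day$events, waveform, fs,
                            seed = NULL, mains_hz = mains_hz,
                            emg_channel = emg_channel)
  rec$light_period_h <- light_period_h
  list(recording = rec, hypnogram = day$hypnogram, events = day$events)
}

#' Export a simulated fixture triad
#'
#' Writes the EDF signal, hypnogram CSV and ground-truth event CSV for one
#' simulated animal. Deterministic given `(seed, profile)`.
#'
#' @param dir output directory (created if missing).
#' @param profile profile name or `strain_profile`.
#' @param seed integer seed.
#' @param duration_h,fs simulation length and rate.
#' @return named character vector of the three paths.
#' @export
export_fixture <- function(dir, profile = "jax_like", seed = 1,
                           duration_h = 24, fs = 100) {
  if (is.character(profile)) profile <- strain_profile(profile)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_recording(profile, duration_h = duration_h, fs = fs,
                            seed = seed)
  paths <- c(
    edf = file.path(dir, sprintf("%s_seed%d.edf", profile$name, seed)),
    hypnogram = file.path(dir, sprintf("%s_seed%d_hypnogram.csv",
                                       profile$name, seed)),
    events = file.path(dir, sprintf("%s_seed%d_events.csv",
                                    profile$name, seed))
  )
  write_edf(sim$recording, paths[["edf"]])
  write_hypnogram(sim$hypnogram, paths[["hypnogram"]])
  write_events(sim$events, paths[["events"]])
  paths
}
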