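# Acquisition-chain filtering (zero-phase digital replica of the analog
# chain: EEG 0.3-70 Hz, EMG high-pass 10 Hz, 50-Hz notch) and robust
# amplitude-based artifact tagging.

#' Filter specification for the acquisition chain
#'
#' Defaults mirror a typical rodent video-EEG/EMG acquisition chain:
#' EEG band-passed 0.3-70 Hz, EMG high-passed at 10 Hz, both notched at
#' 50 Hz (mains). Filters are applied forward-backward (zero phase), so
#' event boundaries are not delayed.
#'
#' @param eeg_hp_hz EEG high-pass corner (Hz).
#' @param eeg_lp_hz EEG low-pass corner (Hz).
#' @param emg_hp_hz EMG high-pass corner (Hz).
#' @param notch_hz notch center frequency (Hz), or `NA` to disable (e.g.
#'   for synthetic data generated without mains interference).
#' @param notch_q quality factor of the notch (center/bandwidth).
#' @export
filter_spec <- function(eeg_hp_hz = 0.3, eeg_lp_hz = 70, emg_hp_hz = 10,
                        notch_hz = 50, notch_q = 30) {
  if (eeg_hp_hz >= eeg_lp_hz) stop("high-pass corner must lie below low-pass corner")
  if (!is.na(notch_hz) && (notch_hz <= eeg_hp_hz || notch_hz >= eeg_lp_hz)) {
    stop("notch frequency must lie inside the EEG pass-band")
  }
  structure(list(eeg_hp_hz = eeg_hp_hz, eeg_lp_hz = eeg_lp_hz,
                 emg_hp_hz = emg_hp_hz, notch_hz = notch_hz,
                 notch_q = notch_q),
            class = "filter_spec")
}

#' Adapt a filter specification to a sampling rate
#'
#' Lowers the EEG low-pass corner to 40% of the sampling rate when the
#' requested corner is not realizable at `fs`, and drops the notch when it
#' lies at or above 45% of `fs`. Used by the pipeline so recordings
#' sampled below the native 400 Hz (e.g. 100 Hz simulations) still pass
#' through an equivalent chain.
#'
#' @param spec a `filter_spec`.
#' @param fs sampling rate (Hz).
#' @export
adapt_filter_spec <- function(spec, fs) {
  if (spec$eeg_lp_hz >= fs / 2) spec$eeg_lp_hz <- 0.4 * fs
  if (!is.na(spec$notch_hz) && spec$notch_hz >= 0.45 * fs) spec$notch_hz <- NA
  spec
}

# RBJ biquad band-stop at f0 with quality q
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

# zero-phase filtering realized in the frequency domain (the |H|^2
# response a forward-backward pass applies), one FFT pass per channel
filter_eeg <- function(x, spec, fs) {
  filters <- list(
    signal::butter(2, spec$eeg_hp_hz / (fs / 2), type = "high"),
    signal::butter(4, spec$eeg_lp_hz / (fs / 2), type = "low")
  )
  if (!is.na(spec$notch_hz)) {
    filters <- c(filters, list(notch_coefs(spec$notch_hz, fs, spec$notch_q)))
  }
  fft_zero_phase(x, fs, filters,
                 cache_key = paste0("eeg", spec$eeg_hp_hz, "-", spec$eeg_lp_hz,
                                    "n", spec$notch_hz))
}

filter_emg <- function(x, spec, fs) {
  filters <- list(signal::butter(4, spec$emg_hp_hz / (fs / 2), type = "high"))
  if (!is.na(spec$notch_hz)) {
    filters <- c(filters, list(notch_coefs(spec$notch_hz, fs, spec$notch_q)))
  }
  fft_zero_phase(x, fs, filters,
                 cache_key = paste0("emg", spec$emg_hp_hz, "n", spec$notch_hz))
}

#' Apply the acquisition-chain filters
#'
#' EEG channels are band-passed and notched, EMG channels high-passed and
#' notched, all zero-phase. Output length equals input length.
#'
#' @param rec a `signal_recording` with `fs > 2 * eeg_lp_hz`.
#' @param spec a `filter_spec`.
#' @return filtered `signal_recording`.
#' @export
apply_acquisition_filters <- function(rec, spec = filter_spec()) {
  if (rec$fs <= 2 * spec$eeg_lp_hz) {
    stop("sampling rate ", rec$fs, " Hz too low for a ", spec$eeg_lp_hz,
         " Hz low-pass; see adapt_filter_spec()")
  }
  rec$channels <- lapply(rec$channels, function(ch) {
    ch$samples <- if (ch$role == "EMG") filter_emg(ch$samples, spec, rec$fs)
                  else filter_eeg(ch$samples, spec, rec$fs)
    ch
  })
  rec
}

#' Tag artifact epochs
#'
#' Relabels as ARTIFACT any epoch whose EEG amplitude exceeds
#' `mad_factor` times the MAD of the whole EEG for at least
#' `min_duration_s` cumulative within the epoch, or that contains clipped
#' samples (at `clip_limit`, if given). The pre-tagging labels are kept in
#' the hypnogram's `original` field; existing ARTIFACT labels are never
#' reverted.
#'
#' @param rec a (filtered) `signal_recording`.
#' @param hyp hypnogram aligned to the recording.
#' @param mad_factor amplitude threshold in MAD units (default 10).
#' @param min_duration_s cumulative supra-threshold time needed to reject
#'   an epoch (default 0.5 s).
#' @param clip_limit absolute amplitude treated as clipping (microvolts),
#'   or `Inf` to disable.
#' @return hypnogram with ARTIFACT labels applied.
#' @export
tag_artifacts <- function(rec, hyp, mad_factor = 10, min_duration_s = 0.5,
                          clip_limit = Inf) {
  x <- get_channel(rec, "EEG")$samples
  thr <- mad_factor * stats::mad(x)
  ep_n <- round(hyp$epoch_len_s * rec$fs)
  n_ep <- min(n_epochs(hyp), length(x) %/% ep_n)
  over <- abs(x[seq_len(n_ep * ep_n)]) > thr
  clip <- abs(x[seq_len(n_ep * ep_n)]) >= clip_limit
  grp <- rep(seq_len(n_ep), each = ep_n)
  over_s <- as.numeric(rowsum(as.numeric(over), grp)) / rec$fs
  clipped <- as.numeric(rowsum(as.numeric(clip), grp)) > 0
  bad <- over_s >= min_duration_s | clipped
  labels <- hyp$labels
  orig <- if (is.null(hyp$original)) hyp$labels else hyp$original
  labels[seq_len(n_ep)][bad] <- "ARTIFACT"
  hypnogram(labels, epoch_len_s = hyp$epoch_len_s, start_zt = hyp$start_zt,
            original = orig)
}
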