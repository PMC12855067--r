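# SignalRecording: multichannel EEG/EMG time series with sampling rate,
# channel roles, and a light-cycle anchor (ZT of sample 0).

CHANNEL_ROLES <- c("EEG_frontal", "EEG_parietal", "EMG")

#' Construct a signal recording
#'
#' A `signal_recording` bundles equal-length EEG/EMG channels sampled at a
#' common rate with the Zeitgeber-time anchor needed for circadian
#' analysis. Samples are in microvolts.
#'
#' @param channels list of channels, each a list with `name` (character),
#'   `role` (one of `"EEG_frontal"`, `"EEG_parietal"`, `"EMG"`) and
#'   `samples` (numeric vector, microvolts).
#' @param fs sampling rate in Hz.
#' @param start_zt hours since lights-on (ZT) at sample 0, in `[0, 24)`.
#' @param light_period_h duration of the lights-on block in hours
#'   (default 12, a 12:12 light/dark cycle).
#' @return object of class `signal_recording`.
#' @export
signal_recording <- function(channels, fs, start_zt = 0, light_period_h = 12) {
  if (length(channels) == 0L) stop("at least one channel is required")
  lens <- vapply(channels, function(ch) length(ch$samples), integer(1))
  if (length(unique(lens)) != 1L) stop("all channels must have the same length")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (start_zt < 0 || start_zt >= 24) stop("start_zt must lie in [0, 24)")
  roles <- vapply(channels, function(ch) ch$role, character(1))
  if (!all(roles %in% CHANNEL_ROLES)) {
    stop("unknown channel role(s): ", paste(setdiff(roles, CHANNEL_ROLES), collapse = ", "))
  }
  structure(
    list(channels = channels, fs = fs, start_zt = start_zt,
         light_period_h = light_period_h),
    class = "signal_recording"
  )
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %d channel(s), %.6g Hz, %.1f s, start ZT %.2f h\n",
              length(x$channels), x$fs, duration_s(x), x$start_zt))
  for (ch in x$channels) {
    cat(sprintf("  %-16s role=%-12s n=%d\n", ch$name, ch$role, length(ch$samples)))
  }
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `signal_recording`.
#' @export
n_samples <- function(rec) length(rec$channels[[1L]]$samples)

#' Recording duration in seconds
#' @param rec a `signal_recording`.
#' @export
duration_s <- function(rec) n_samples(rec) / rec$fs

#' Extract a channel by role
#'
#' Returns the first channel with the requested role. For `"EEG"` the
#' frontal derivation is preferred (the derivation used for discharge
#' detection), falling back to parietal.
#'
#' @param rec a `signal_recording`.
#' @param role `"EEG_frontal"`, `"EEG_parietal"`, `"EMG"`, or `"EEG"`.
#' @export
get_channel <- function(rec, role) {
  roles <- vapply(rec$channels, function(ch) ch$role, character(1))
  if (role == "EEG") {
    i <- which(roles == "EEG_frontal")
    if (length(i) == 0L) i <- which(roles == "EEG_parietal")
  } else {
    i <- which(roles == role)
  }
  if (length(i) == 0L) stop("no channel with role ", role)
  rec$channels[[i[1L]]]
}

# Mapping from EDF channel labels to roles. First match wins; a label
# matching none (or an EEG label matching both EEG patterns) is an error
# surfaced by the caller.
infer_channel_role <- function(label) {
  l <- tolower(label)
  if (grepl("emg", l)) return("EMG")
  if (grepl("front", l)) return("EEG_frontal")
  if (grepl("pariet", l)) return("EEG_parietal")
  if (grepl("eeg", l)) return("EEG_frontal")
  NA_character_
}
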