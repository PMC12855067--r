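# Rule-based vigilance-state scoring: WAKE by muscle tone, then SWS by
# delta dominance, then REM by theta/delta ratio. A transparent surrogate
# for visual staging whose errors are measurable against generator truth.

#' Per-epoch scoring features
#'
#' Band powers come from the per-epoch Welch PSD (2-s Hanning windows,
#' 0.5-s overlap, the same estimator used for event spectra); EMG tone is
#' the per-epoch RMS. Bands: delta 0.5-4 Hz, theta 5-9 Hz, total
#' 0.5-30 Hz.
#'
#' @param rec a (filtered) `signal_recording` with EEG and EMG channels.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param epoch_psd optional precomputed `epoch_psd_matrix()` of the EEG
#'   channel (shared with `reference_psd()` by the pipeline).
#' @return data.frame with one row per epoch: `delta`, `theta`, `total`,
#'   `delta_frac`, `theta_delta_ratio` (`Inf` when delta is 0), `emg_rms`.
#' @export
extract_features <- function(rec, epoch_len_s = 10, epoch_psd = NULL) {
  eeg <- get_channel(rec, "EEG")$samples
  emg <- tryCatch(get_channel(rec, "EMG")$samples, error = function(e) NULL)
  if (is.null(emg)) {
    stop("scoring requires an EMG channel: WAKE/REM cannot be separated ",
         "from EEG alone")
  }
  ep <- if (is.null(epoch_psd)) {
    epoch_psd_matrix(eeg, rec$fs, epoch_len_s = epoch_len_s)
  } else epoch_psd
  delta <- band_power(ep$freq, ep$psd, 0.5, 4)
  theta <- band_power(ep$freq, ep$psd, 5, 9)
  total <- band_power(ep$freq, ep$psd, 0.5, 30)
  n_ep <- nrow(ep$psd)
  ep_n <- round(epoch_len_s * rec$fs)
  grp <- rep(seq_len(n_ep), each = ep_n)
  emg_rms <- sqrt(as.numeric(rowsum(emg[seq_len(n_ep * ep_n)]^2, grp)) / ep_n)
  data.frame(
    epoch = seq_len(n_ep),
    delta = delta, theta = theta, total = total,
    delta_frac = ifelse(total > 0, delta / total, 0),
    theta_delta_ratio = ifelse(delta > 0, theta / delta, Inf),
    emg_rms = emg_rms
  )
}

#' Auto-calibrated scoring thresholds
#'
#' EMG threshold: midpoint of the two centers of a 2-class 1-D k-means on
#' log EMG RMS (the distribution is bimodal when both sleep and wake are
#' present); if the separation is too small the fixed fallback is used
#' with a warning. Delta threshold: 60th percentile of the delta fraction
#' over sleep-candidate epochs. REM threshold: theta/delta ratio 2.
#'
#' @param features output of `extract_features()`.
#' @param fallback_emg fixed EMG RMS threshold used when the log-RMS
#'   distribution is not bimodal.
#' @return list with `emg_thr`, `delta_thr`, `ratio_thr`.
#' @export
auto_thresholds <- function(features, fallback_emg = 15) {
  lr <- log(pmax(features$emg_rms, 1e-12))
  km <- stats::kmeans(lr, centers = 2, nstart = 5)
  ctr <- sort(km$centers[, 1])
  if (diff(ctr) < 0.5) {
    warning("EMG log-RMS distribution not bimodal; using fixed EMG threshold")
    emg_thr <- fallback_emg
  } else {
    emg_thr <- exp(mean(ctr))
  }
  sleepish <- features$emg_rms <= emg_thr
  delta_thr <- if (any(sleepish)) {
    stats::quantile(features$delta_frac[sleepish], 0.6, names = FALSE)
  } else 0.5
  list(emg_thr = emg_thr, delta_thr = delta_thr, ratio_thr = 2)
}

#' Score epochs from features
#'
#' Decision rules, in order: WAKE if EMG RMS exceeds the EMG threshold;
#' else SWS if the delta fraction reaches the delta threshold; else REM if
#' theta/delta reaches the ratio threshold; else SWS. ARTIFACT labels from
#' an optional reference hypnogram are passed through.
#'
#' @param features output of `extract_features()`.
#' @param thresholds `"auto"` or a list with `emg_thr`, `delta_thr`,
#'   `ratio_thr`.
#' @param start_zt ZT of the first epoch.
#' @param epoch_len_s epoch length (s).
#' @param artifact_from optional `hypnogram` whose ARTIFACT epochs are
#'   propagated into the result.
#' @return a `hypnogram`.
#' @export
score_epochs <- function(features, thresholds = "auto", start_zt = 0,
                         epoch_len_s = 10, artifact_from = NULL) {
  if (identical(thresholds, "auto")) thresholds <- auto_thresholds(features)
  labels <- ifelse(
    features$emg_rms > thresholds$emg_thr, "WAKE",
    ifelse(features$delta_frac >= thresholds$delta_thr, "SWS",
           ifelse(features$theta_delta_ratio >= thresholds$ratio_thr,
                  "REM", "SWS"))
  )
  if (!is.null(artifact_from)) {
    n <- min(length(labels), n_epochs(artifact_from))
    art <- which(artifact_from$labels[seq_len(n)] == "ARTIFACT")
    labels[art] <- "ARTIFACT"
  }
  hypnogram(labels, epoch_len_s = epoch_len_s, start_zt = start_zt)
}

#' Score a recording
#'
#' Convenience wrapper: features then rules. The recording should already
#' be filtered.
#' @inheritParams extract_features
#' @inheritParams score_epochs
#' @export
score_recording <- function(rec, epoch_len_s = 10, thresholds = "auto",
                            artifact_from = NULL) {
  feats <- extract_features(rec, epoch_len_s)
  score_epochs(feats, thresholds, start_zt = rec$start_zt,
               epoch_len_s = epoch_len_s, artifact_from = artifact_from)
}

#' Compare a scored hypnogram with a reference
#'
#' @param pred,truth hypnograms with equal epoch counts.
#' @return list with overall `accuracy`, Cohen's `kappa`, the confusion
#'   `table`, and per-state `precision`/`recall`.
#' @export
evaluate_scoring <- function(pred, truth) {
  if (n_epochs(pred) != n_epochs(truth)) {
    stop("hypnograms have different epoch counts")
  }
  lev <- c("WAKE", "SWS", "REM")
  keep <- pred$labels != "ARTIFACT" & truth$labels != "ARTIFACT"
  p <- factor(pred$labels[keep], levels = lev)
  t <- factor(truth$labels[keep], levels = lev)
  tab <- table(truth = t, pred = p)
  n <- sum(tab)
  acc <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 1
  precision <- diag(tab) / pmax(colSums(tab), 1)
  recall <- diag(tab) / pmax(rowSums(tab), 1)
  list(accuracy = acc, kappa = kappa, table = tab,
       precision = precision, recall = recall)
}
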