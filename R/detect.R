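# Two-stage spike-and-wave discharge detection: a permissive candidate
# pass (supra-threshold analytic envelope in the 3-20 Hz band, merged
# across brief gaps) followed by acceptance filtering on the amplitude
# and cycle criteria (>= 1.5 x background, >= 4 cycles at a plausible
# cycle period) plus a rhythmicity criterion (autocorrelation at the
# candidate's own cycle period) that stands in for the visual curation
# step used with real recordings: amplitude bursts of filtered noise pass
# the permissive criteria in large numbers but are arrhythmic, exactly
# the events a human reviewer discards.

#' Detection parameters
#'
#' @param band detection band in Hz (brackets the ~6.7 and ~13.3 Hz
#'   discharge peaks with margin).
#' @param threshold_factor amplitude criterion relative to background
#'   (1.5).
#' @param min_cycles minimum number of supra-threshold cycles (4).
#' @param cycle_period_bounds admissible intervals between successive
#'   cycle peaks, in seconds (follows the band: 1/20 to 1/3 s).
#' @param background_window_s rolling background window (s).
#' @param bg_block_s block length for the background median (s); the
#'   background is piecewise constant at this resolution.
#' @param merge_gap_s candidates closer than this are merged before the
#'   cycle test (s).
#' @param envelope_smooth_s moving-average smoothing of the analytic
#'   envelope (s); averages out the sub-cycle beat of the two-component
#'   discharge waveform.
#' @param min_rhythmicity minimum autocorrelation of the band-passed
#'   event segment at its own cycle period (evaluated at one and two
#'   periods, the smaller of the two); the automated stand-in for visual
#'   rejection of arrhythmic noise bursts. Set to 0 to disable and obtain
#'   the fully permissive detector.
#' @param min_span_s minimum time spanned by the accepted cycle run (s);
#'   rhythmic runs shorter than this are still noise-like at the cycle
#'   periods admissible here.
#' @param min_harmonic_ratio spike-sharpness criterion: minimum power near
#'   twice the dominant frequency relative to power at the dominant
#'   frequency. Spike-wave complexes are sharp, so they carry a strong
#'   second spectral component; smooth narrow-band oscillations (e.g.
#'   theta bursts) do not. Set to 0 to disable.
#' @param rescue_ratio,rescue_rhythmicity second acceptance route: events
#'   whose envelope exceeds `rescue_ratio` times background are accepted
#'   at the relaxed `rescue_rhythmicity` bar, since brief events depress
#'   the autocorrelation criterion while amplitudes that large do not
#'   occur in stationary background.
#' @param boundary_search_s how far beyond the first/last supra-threshold
#'   peak to look for the bounding zero crossings (s).
#' @export
detection_params <- function(band = c(3, 20), threshold_factor = 1.5,
                             min_cycles = 4,
                             cycle_period_bounds = c(1 / 20, 1 / 3),
                             background_window_s = 60, bg_block_s = 1,
                             merge_gap_s = 0.3, envelope_smooth_s = 0.15,
                             min_rhythmicity = 0.65, min_span_s = 0.45,
                             min_harmonic_ratio = 0.08,
                             rescue_ratio = 4.5, rescue_rhythmicity = 0.4,
                             boundary_search_s = 0.5) {
  if (threshold_factor <= 1) stop("threshold_factor must exceed 1")
  if (min_cycles < 1) stop("min_cycles must be >= 1")
  structure(list(band = band, threshold_factor = threshold_factor,
                 min_cycles = min_cycles,
                 cycle_period_bounds = cycle_period_bounds,
                 background_window_s = background_window_s,
                 bg_block_s = bg_block_s, merge_gap_s = merge_gap_s,
                 envelope_smooth_s = envelope_smooth_s,
                 min_rhythmicity = min_rhythmicity, min_span_s = min_span_s,
                 min_harmonic_ratio = min_harmonic_ratio,
                 rescue_ratio = rescue_ratio,
                 rescue_rhythmicity = rescue_rhythmicity,
                 boundary_search_s = boundary_search_s),
            class = "detection_params")
}

band_filter <- function(x, fs, band) {
  Re(fft_band_analytic(x, fs, band))
}

#' Background envelope level
#'
#' Per-sample background = rolling median (over `background_window_s`) of
#' the band-passed signal's analytic envelope, computed on
#' `bg_block_s`-block envelope levels with ARTIFACT epochs excluded, then
#' expanded back to samples. Floored at a small positive epsilon. The
#' median is taken across blocks, so brief discharges (2-3 blocks of a
#' 60-block window) cannot inflate the background.
#'
#' @param rec a filtered `signal_recording` (or a numeric envelope via
#'   `env`).
#' @param hyp hypnogram with artifact epochs tagged.
#' @param params a `detection_params`.
#' @param env optional precomputed envelope (internal reuse).
#' @return numeric vector of per-sample background levels.
#' @export
estimate_background <- function(rec, hyp, params = detection_params(),
                                env = NULL) {
  fs <- rec$fs
  if (is.null(env)) {
    env <- Mod(fft_band_analytic(get_channel(rec, "EEG")$samples, fs,
                                 params$band))
  }
  n <- length(env)
  blk <- max(1L, round(params$bg_block_s * fs))
  n_blk <- n %/% blk
  if (n_blk < 1L) stop("recording too short for background estimation")
  bm <- blocked_mean(env[seq_len(n_blk * blk)], blk)
  # mask blocks inside ARTIFACT epochs
  blk_t <- ((seq_len(n_blk)) - 0.5) * blk / fs
  art <- hyp$labels[epoch_of(hyp, blk_t)] == "ARTIFACT"
  if (all(art)) stop("no background available: every epoch is ARTIFACT")
  bm_clean <- bm
  bm_clean[art] <- NA
  # fill masked blocks by interpolation so the rolling window stays causal
  if (any(art)) {
    ok <- which(!art)
    bm_clean <- stats::approx(ok, bm[ok], xout = seq_len(n_blk),
                              rule = 2)$y
  }
  k <- round(params$background_window_s / params$bg_block_s)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n_blk %% 2L == 0L) n_blk - 1L else n_blk)
  bg_blk <- if (k >= 3L) stats::runmed(bm_clean, k, endrule = "median")
            else bm_clean
  bg <- rep(bg_blk, each = blk)
  bg <- c(bg, rep(bg[length(bg)], n - length(bg)))
  pmax(as.numeric(bg), 1e-9)
}

# per-block envelope level; the robust (median) statistic is applied at
# the 60-s window across blocks, where outlier rejection matters -- a
# discharge spans only 2-3 one-second blocks and cannot move the window
# median, so the cheap within-block mean loses nothing
blocked_mean <- function(x, blk) {
  n_blk <- length(x) %/% blk
  grp <- rep(seq_len(n_blk), each = blk)
  as.numeric(rowsum(x[seq_len(n_blk * blk)], grp)) / blk
}

#' Detect spike-and-wave discharges
#'
#' Runs the full detection chain on the EEG channel: band-pass, smoothed
#' analytic envelope, rolling-median background, supra-threshold cores
#' merged across gaps shorter than `merge_gap_s`, cycle counting
#' (supra-threshold oscillation peaks at admissible intervals), the
#' amplitude/cycle acceptance criteria, the rhythmicity and
#' spike-sharpness curation surrogates (with a relaxed rhythmicity bar
#' for very-high-amplitude events), and boundary refinement to the zero
#' crossings bracketing the first/last run peak. Accepted events are
#' attributed to the vigilance state of their onset epoch.
#'
#' @param rec a filtered `signal_recording`.
#' @param hyp hypnogram (artifact epochs excluded from background and
#'   attribution).
#' @param params a `detection_params`.
#' @param return_candidates if `TRUE`, attach the permissive candidate
#'   table as attribute `"candidates"`.
#' @return an `event_table` with provenance `"detected"`.
#' @export
detect_swd <- function(rec, hyp, params = detection_params(),
                       return_candidates = FALSE) {
  fs <- rec$fs
  eeg <- get_channel(rec, "EEG")$samples
  xa <- fft_band_analytic(eeg, fs, params$band)
  xb <- Re(xa)
  env <- Mod(xa)
  rm(xa)
  env_s <- moving_average(env, round(params$envelope_smooth_s * fs))
  bg <- estimate_background(rec, hyp, params, env = env)
  thr <- params$threshold_factor * bg

  above <- env_s >= thr
  runs <- logical_runs(above)
  if (nrow(runs) == 0L) {
    return(finish_events(numeric(0), numeric(0), integer(0), numeric(0),
                         hyp, rec))
  }
  # merge cores separated by less than the merge gap
  gap <- round(params$merge_gap_s * fs)
  merged <- merge_runs(runs, gap)

  # supra-threshold oscillation peaks of the band-passed signal
  pk <- which(diff(sign(diff(xb))) < 0) + 1L
  pk <- pk[xb[pk] >= thr[pk]]

  nm <- nrow(merged)
  onset <- offset <- ratio <- numeric(nm)
  cyc <- integer(nm)
  keep <- logical(nm)
  cand_cyc <- integer(nm)
  cand_span <- cand_rhy <- rep(NA_real_, nm)
  # assign peaks to merged regions and pre-filter regions that cannot
  # contain an acceptable run (too few peaks or too short a span)
  reg_of_pk <- findInterval(pk, merged$start)
  in_reg <- reg_of_pk >= 1L & pk <= merged$end[pmax(reg_of_pk, 1L)]
  pkk <- pk[in_reg]
  reg <- reg_of_pk[in_reg]
  min_span_n <- params$min_span_s * fs
  cnt <- tabulate(reg, nbins = nm)
  first_pk <- last_pk <- rep(NA_integer_, nm)
  fd <- !duplicated(reg)
  first_pk[reg[fd]] <- pkk[fd]
  ld <- !duplicated(reg, fromLast = TRUE)
  last_pk[reg[ld]] <- pkk[ld]
  eligible <- which(cnt >= params$min_cycles &
                      (last_pk - first_pk) >= min_span_n)
  pk_by_reg <- split(pkk, factor(reg, levels = seq_len(nm)))
  for (i in eligible) {
    p <- pk_by_reg[[i]]
    run0 <- longest_cycle_run(p, fs, params$cycle_period_bounds)
    # strict trim for the rhythmicity core (keeps the period estimate
    # clean of chained noise cycles), then re-extend the boundaries over
    # edge cycles that continue the core's rhythm
    core <- trim_run_ends(run0, xb, frac = 0.60)
    run <- extend_core(run0, core, xb)
    span_s <- if (length(run) > 1L) (run[length(run)] - run[1L]) / fs else 0
    cand_cyc[i] <- length(run)
    cand_span[i] <- span_s
    if (length(run) < params$min_cycles) next
    if (span_s < params$min_span_s) next
    bounds <- zero_cross_bounds(xb, run[1L], run[length(run)],
                                round(params$boundary_search_s * fs))
    on_i <- bounds[1L]; off_i <- bounds[2L]
    amp_ratio <- max(env_s[on_i:off_i] / bg[on_i:off_i])
    if (params$min_rhythmicity > 0) {
      core_b <- zero_cross_bounds(xb, core[1L], core[length(core)],
                                  round(params$boundary_search_s * fs))
      rhy <- rhythmicity(xb[core_b[1L]:core_b[2L]], core)
      cand_rhy[i] <- rhy
      if (is.na(rhy)) next
      # short events depress the autocorrelation at the two-period lag;
      # amplitudes this far above background do not occur in stationary
      # noise, so such events are accepted at a relaxed rhythmicity bar
      rescue <- amp_ratio >= params$rescue_ratio &&
        rhy >= params$rescue_rhythmicity
      if (rhy < params$min_rhythmicity && !rescue) next
    }
    if (params$min_harmonic_ratio > 0 &&
        !harmonic_check(eeg[on_i:off_i], fs, params$band,
                        params$min_harmonic_ratio)) next
    keep[i] <- TRUE
    onset[i] <- (on_i - 1L) / fs
    offset[i] <- off_i / fs
    cyc[i] <- length(run)
    ratio[i] <- amp_ratio
  }
  ev <- finish_events(onset[keep], offset[keep], cyc[keep], ratio[keep],
                      hyp, rec)
  if (return_candidates) {
    attr(ev, "candidates") <- data.frame(
      onset_s = (merged$start - 1L) / fs, offset_s = merged$end / fs,
      n_cycles = cand_cyc, span_s = cand_span, rhythmicity = cand_rhy)
  }
  ev
}

# autocorrelation of the event segment at the run's own median cycle
# period L, evaluated at lags L and 2L (minimum of the two); rhythmic
# discharges stay phase-locked over two periods, noise bursts do not
rhythmicity <- function(seg, run) {
  if (length(run) < 2L) return(NA_real_)
  iv <- diff(run)
  n <- length(seg)
  # candidate cycle periods: the run intervals can reflect the true cycle,
  # half of it (a strong second spectral component doubles the peaks), or
  # twice it (weak alternate cycles), and single freak intervals must not
  # dominate — so derive hypotheses from both the overall median and the
  # fastest-cluster median, each at x0.5 / x1 / x2
  L1 <- stats::median(iv)
  L2 <- stats::median(iv[iv <= 1.4 * min(iv)])
  periods <- unique(as.integer(round(c(L1, 2 * L1, L1 / 2,
                                       L2, 2 * L2, L2 / 2))))
  periods <- periods[periods >= 4L & periods + 2L < n]
  if (length(periods) == 0L) return(NA_real_)
  x <- seg - mean(seg)
  v <- sum(x^2) / n
  if (v <= 0) return(0)
  # 1/n-normalized autocorrelation: conservative on purpose -- the
  # taper toward long lags suppresses the noisy estimates short noise
  # bursts produce there. Short genuine events pay the same price; the
  # high-amplitude acceptance route in detect_swd() covers them.
  ac_at <- function(k) sum(x[1:(n - k)] * x[(k + 1L):n]) / (n * v)
  best <- NA_real_
  for (P in periods) {
    lags <- c(P, 2L * P)
    lags <- lags[lags >= 2L & lags <= n - 3L]
    if (length(lags) == 0L) next
    s <- min(vapply(lags, ac_at, numeric(1)))
    best <- if (is.na(best)) s else max(best, s)
  }
  best
}

finish_events <- function(onset, offset, cyc, ratio, hyp, rec) {
  if (length(onset) == 0L) {
    return(event_table())
  }
  # overlapping refined boundaries collapse to one event
  keep <- rep(TRUE, length(onset))
  for (i in seq_along(onset)[-1L]) {
    if (onset[i] < max(offset[seq_len(i - 1L)][keep[seq_len(i - 1L)]])) {
      keep[i] <- FALSE
    }
  }
  onset <- onset[keep]; offset <- offset[keep]
  cyc <- cyc[keep]; ratio <- ratio[keep]
  st <- hyp$labels[epoch_of(hyp, onset)]
  event_table(onset, offset, channel = get_channel(rec, "EEG")$name,
              state = st, onset_zt_h = zt_at(onset, rec$start_zt),
              provenance = "detected", n_cycles = cyc,
              peak_amplitude_ratio = ratio)
}

logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  new_grp <- c(TRUE, runs$start[-1L] - runs$end[-nrow(runs)] - 1L >= gap)
  grp <- cumsum(new_grp)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(start = runs$start[new_grp], end = runs$end[last])
}

# longest run of peaks whose successive intervals all lie within bounds;
# returns the peak indices of that run
longest_cycle_run <- function(p, fs, bounds) {
  if (length(p) == 0L) return(integer(0))
  if (length(p) == 1L) return(p)
  ok <- diff(p) / fs >= bounds[1L] & diff(p) / fs <= bounds[2L]
  r <- rle(ok)
  if (!any(r$values)) return(p[1L])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- which.max(ifelse(r$values, r$lengths, 0L))
  p[starts[best]:(ends[best] + 1L)]
}

# drop leading/trailing run peaks far below the run's typical amplitude:
# they are threshold-grazing noise cycles chained onto the discharge, and
# they corrupt both the marked boundaries and the cycle-period estimate
trim_run_ends <- function(run, x, frac = 0.45, min_keep = 3L) {
  if (length(run) <= min_keep) return(run)
  while (length(run) > min_keep &&
         x[run[1L]] < frac * stats::median(x[run])) {
    run <- run[-1L]
  }
  while (length(run) > min_keep &&
         x[run[length(run)]] < frac * stats::median(x[run])) {
    run <- run[-length(run)]
  }
  run
}

# re-admit edge peaks beyond the strict core while they continue the
# core's cycle period (or its double, for weak alternate cycles) at a
# non-negligible amplitude: genuine onset/offset cycles do, chained
# noise cycles rarely do
extend_core <- function(run0, core, x, frac = 0.40) {
  if (length(core) < 2L) return(core)
  L <- stats::median(diff(core))
  medamp <- stats::median(x[core])
  ok <- function(d) (d >= 0.8 * L && d <= 1.2 * L) ||
    (d >= 1.6 * L && d <= 2.4 * L)
  left <- integer(0)
  cur <- core[1L]
  for (p in rev(run0[run0 < core[1L]])) {
    if (ok(cur - p) && x[p] >= frac * medamp) {
      left <- c(p, left)
      cur <- p
    } else break
  }
  right <- integer(0)
  cur <- core[length(core)]
  for (p in run0[run0 > core[length(core)]]) {
    if (ok(p - cur) && x[p] >= frac * medamp) {
      right <- c(right, p)
      cur <- p
    } else break
  }
  c(left, core, right)
}

zero_cross_bounds <- function(x, first_pk, last_pk, search) {
  n <- length(x)
  lo <- max(1L, first_pk - search)
  seg <- x[lo:first_pk]
  zc <- which(seg[-length(seg)] * seg[-1L] <= 0)
  on_i <- if (length(zc) > 0L) lo + max(zc) - 1L else lo
  hi <- min(n, last_pk + search)
  seg <- x[last_pk:hi]
  zc <- which(seg[-length(seg)] * seg[-1L] <= 0)
  off_i <- if (length(zc) > 0L) last_pk + min(zc) else hi
  c(on_i, off_i)
}

# spike-sharpness: power near twice the dominant in-band frequency must
# not be negligible relative to the dominant component itself
harmonic_check <- function(seg, fs, band, min_ratio) {
  p <- welch_psd(seg, fs)
  sel <- p$freq >= band[1L] & p$freq <= band[2L]
  fd <- p$freq[sel][which.max(p$psd[sel])]
  if (2 * fd >= 0.9 * fs / 2) return(TRUE)  # second component unobservable
  base <- sum(p$psd[p$freq >= 0.75 * fd & p$freq <= 1.25 * fd])
  harm <- sum(p$psd[p$freq >= 1.7 * fd & p$freq <= 2.3 * fd])
  if (base <= 0) return(FALSE)
  harm / base >= min_ratio
}

#' Compare detected events with ground truth
#'
#' Events match when their intervals overlap by at least half the shorter
#' event, or when onsets agree within `tolerance_s`. Matching is greedy in
#' onset order, one-to-one.
#'
#' @param detected,truth `event_table`s on the same recording.
#' @param tolerance_s onset tolerance in seconds.
#' @return list with `recall`, `precision`, `onset_mae_s`, `n_matched`.
#' @export
evaluate_detection <- function(detected, truth, tolerance_s = 0.5) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nt == 0L) {
    return(list(recall = NA_real_, precision = if (nd == 0L) NA_real_ else 0,
                onset_mae_s = NA_real_, n_matched = 0L))
  }
  used <- rep(FALSE, nd)
  err <- numeric(0)
  matched <- 0L
  for (i in seq_len(nt)) {
    best <- 0L; best_ov <- -Inf
    for (j in seq_len(nd)) {
      if (used[j]) next
      ov <- min(truth$offset_s[i], detected$offset_s[j]) -
        max(truth$onset_s[i], detected$onset_s[j])
      shorter <- min(truth$offset_s[i] - truth$onset_s[i],
                     detected$offset_s[j] - detected$onset_s[j])
      hit <- ov >= 0.5 * shorter ||
        abs(truth$onset_s[i] - detected$onset_s[j]) <= tolerance_s
      if (hit && ov > best_ov) {
        best <- j; best_ov <- ov
      }
    }
    if (best > 0L) {
      used[best] <- TRUE
      matched <- matched + 1L
      err <- c(err, abs(truth$onset_s[i] - detected$onset_s[best]))
    }
  }
  list(recall = matched / nt,
       precision = if (nd > 0L) matched / nd else NA_real_,
       onset_mae_s = if (matched > 0L) mean(err) else NA_real_,
       n_matched = matched)
}

#' Export a review bundle for (simulated) visual curation
#'
#' Writes one trace-snippet CSV (and, if `plots = TRUE`, a PNG) per event
#' plus an accept/reject template CSV. Re-importing the filled template
#' with `apply_review()` yields the curated table.
#'
#' @param rec a `signal_recording`.
#' @param events an `event_table`.
#' @param dir output directory.
#' @param window_s context shown around each event (s).
#' @param plots whether to render PNG snippets.
#' @return the directory path, invisibly.
#' @export
export_review <- function(rec, events, dir, window_s = 5, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(events) == 0L) {
    warning("no events to review; writing empty template")
  }
  eeg <- get_channel(rec, "EEG")$samples
  fs <- rec$fs
  for (i in seq_len(nrow(events))) {
    a <- max(1L, floor((events$onset_s[i] - window_s / 2) * fs))
    b <- min(length(eeg), ceiling((events$offset_s[i] + window_s / 2) * fs))
    snip <- data.frame(t_s = (a:b - 1L) / fs, eeg_uv = eeg[a:b])
    utils::write.csv(snip, file.path(dir, sprintf("event_%04d.csv", i)),
                     row.names = FALSE)
    if (plots) {
      grDevices::png(file.path(dir, sprintf("event_%04d.png", i)),
                     width = 800, height = 300)
      plot(snip$t_s, snip$eeg_uv, type = "l", xlab = "time (s)",
           ylab = "EEG (uV)",
           main = sprintf("event %d: %.2f-%.2f s", i, events$onset_s[i],
                          events$offset_s[i]))
      graphics::abline(v = c(events$onset_s[i], events$offset_s[i]),
                       col = "red")
      grDevices::dev.off()
    }
  }
  template <- data.frame(
    event_id = seq_len(nrow(events)),
    onset_s = events$onset_s, offset_s = events$offset_s,
    n_cycles = events$n_cycles,
    peak_amplitude_ratio = round(events$peak_amplitude_ratio, 3),
    decision = rep("accept", nrow(events))
  )
  utils::write.csv(template, file.path(dir, "review_template.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Apply curation decisions
#'
#' @param events the reviewed `event_table`.
#' @param template data.frame (or CSV path) with `event_id` and
#'   `decision` (`"accept"`/`"reject"`).
#' @return curated `event_table` (provenance `"curated"`).
#' @export
apply_review <- function(events, template) {
  if (is.character(template)) template <- utils::read.csv(template)
  keep <- template$event_id[tolower(template$decision) != "reject"]
  out <- events[seq_len(nrow(events)) %in% keep, , drop = FALSE]
  out$provenance <- rep("curated", nrow(out))
  validate_event_table(as.data.frame(out))
}
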