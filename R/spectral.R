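# Per-event power spectra: Welch estimate on the event segment,
# normalization against the whole-recording artifact-free PSD, rescaling
# to percentage of total, and extraction of the two characteristic peaks.

SPECTRUM_GRID <- seq(0.5, 30, by = 0.1)

#' Welch PSD of one event segment
#'
#' 2-s Hanning windows with 0.5-s overlap; events shorter than one window
#' use a single Hanning window of the event length. The FFT is
#' zero-padded so the native grid is at most 0.1 Hz.
#'
#' @param rec a `signal_recording`.
#' @param event one-row `event_table` (or a list with `onset_s`,
#'   `offset_s`).
#' @return list with `freq` and `psd`.
#' @export
event_psd <- function(rec, event) {
  fs <- rec$fs
  if (event$offset_s > duration_s(rec) + 1e-9 || event$onset_s < 0) {
    stop("event lies outside the recording")
  }
  a <- floor(event$onset_s * fs) + 1L
  b <- min(n_samples(rec), ceiling(event$offset_s * fs))
  if ((b - a + 1L) / fs < 0.25) {
    stop("event too short for spectral estimation")
  }
  welch_psd(get_channel(rec, "EEG")$samples[a:b], fs)
}

#' Whole-recording reference PSD
#'
#' Welch PSD over all artifact-free epochs (same estimator settings as
#' `event_psd()`; windows do not span epoch boundaries, so the estimate
#' equals Welch on the concatenated artifact-free signal restricted to
#' within-epoch windows).
#'
#' @param rec a `signal_recording`.
#' @param hyp hypnogram with artifact epochs tagged.
#' @param epoch_psd optional precomputed `epoch_psd_matrix()` result
#'   (reused from feature extraction).
#' @return list with `freq` and `psd`.
#' @export
reference_psd <- function(rec, hyp, epoch_psd = NULL) {
  if (is.null(epoch_psd)) {
    epoch_psd <- epoch_psd_matrix(get_channel(rec, "EEG")$samples, rec$fs,
                                  epoch_len_s = hyp$epoch_len_s)
  }
  n_ep <- min(nrow(epoch_psd$psd), n_epochs(hyp))
  ok <- which(hyp$labels[seq_len(n_ep)] != "ARTIFACT")
  if (length(ok) == 0L) stop("no artifact-free epochs for the reference PSD")
  list(freq = epoch_psd$freq,
       psd = colMeans(epoch_psd$psd[ok, , drop = FALSE]))
}

#' Normalize an event PSD against the reference
#'
#' Ratio-first, then rescale: the event PSD is divided bin-wise by the
#' reference (floored at its within-band 1st percentile to avoid division
#' blow-up), interpolated onto the common 0.1-Hz grid over 0.5-30 Hz, and
#' rescaled so the normalized power sums to 100 (percent of total). Both
#' intermediate products are retained.
#'
#' @param ev_psd event PSD (`event_psd()` output).
#' @param ref_psd reference PSD (`reference_psd()` output).
#' @return object of class `normalized_spectrum` with `freq`,
#'   `power_pct`, `raw`, `reference`, and (after `extract_peaks()`)
#'   `peak1_hz`, `peak2_hz`.
#' @export
normalize_spectrum <- function(ev_psd, ref_psd) {
  ev <- interp_grid(ev_psd)
  ref <- interp_grid(ref_psd)
  floor_val <- stats::quantile(ref, 0.01, names = FALSE)
  ratio <- ev / pmax(ref, floor_val)
  tot <- sum(ratio)
  pct <- if (tot > 0) 100 * ratio / tot else ratio
  structure(list(freq = SPECTRUM_GRID, power_pct = pct, raw = ev,
                 reference = ref, peak1_hz = NA_real_, peak2_hz = NA_real_),
            class = "normalized_spectrum")
}

interp_grid <- function(p) {
  if (length(p$freq) == length(SPECTRUM_GRID) &&
      isTRUE(all.equal(p$freq, SPECTRUM_GRID))) {
    return(p$psd)
  }
  if (min(p$freq) > SPECTRUM_GRID[1L] || max(p$freq) < 30) {
    stop("PSD grid does not cover 0.5-30 Hz")
  }
  stats::approx(p$freq, p$psd, xout = SPECTRUM_GRID)$y
}

#' Extract the two characteristic spectral peaks
#'
#' Finds the two most prominent local maxima of the normalized spectrum
#' within `band` (prominence over a running-median baseline), refines
#' each by quadratic interpolation over the three bins around the
#' maximum, and returns them in ascending frequency. With fewer than two
#' prominent peaks the missing ones are `NA`.
#'
#' @param spec a `normalized_spectrum` (or any list with `freq` and
#'   `power_pct`).
#' @param band search band in Hz.
#' @param prominence_floor minimum prominence, as a multiple of the flat
#'   (uniform) per-bin share.
#' @return the input with `peak1_hz`/`peak2_hz` filled in.
#' @export
extract_peaks <- function(spec, band = c(3, 20), prominence_floor = 0.5) {
  sel <- which(spec$freq >= band[1L] & spec$freq <= band[2L])
  f <- spec$freq[sel]
  y <- spec$power_pct[sel]
  base <- stats::runmed(y, min(31L, odd_below(length(y))), endrule = "median")
  prom <- y - base
  # the floor scales with the spectrum's own mean level, so the rule works
  # identically for percent-normalized spectra and raw PSDs
  floor_val <- prominence_floor * mean(spec$power_pct)
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  cand <- which(is_max & prom > floor_val)
  peaks <- rep(NA_real_, 2L)
  if (length(cand) > 0L) {
    ord <- cand[order(prom[cand], decreasing = TRUE)]
    picked <- ord[1L]
    # second peak must be a distinct component, not the same lobe, and
    # prominent in its own right (window sidelobes are ~0.1% of the
    # main lobe; a genuine second component is far above 5%)
    for (j in ord[-1L]) {
      if (abs(f[j] - f[picked[1L]]) > 1.5 &&
          prom[j] >= 0.05 * prom[picked[1L]]) {
        picked <- c(picked, j)
        break
      }
    }
    refined <- vapply(picked, function(i) quad_refine(f, y, i), numeric(1))
    peaks[seq_along(refined)] <- sort(refined)
    if (length(refined) == 1L) peaks <- c(refined, NA_real_)
  }
  spec$peak1_hz <- peaks[1L]
  spec$peak2_hz <- peaks[2L]
  spec
}

odd_below <- function(n) if (n %% 2L == 0L) n - 1L else n

quad_refine <- function(f, y, i) {
  if (i <= 1L || i >= length(y)) return(f[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den == 0) return(f[i])
  f[i] + 0.5 * (y1 - y3) / den * (f[2L] - f[1L])
}

#' Normalized spectra for every event of a recording
#'
#' @param rec a filtered `signal_recording`.
#' @param events an `event_table`.
#' @param hyp hypnogram (for the artifact-free reference).
#' @param band peak-search band.
#' @return list of `normalized_spectrum` objects (with peaks extracted),
#'   one per event; events too short for estimation are `NULL`.
#' @export
event_spectra <- function(rec, events, hyp, band = c(3, 20)) {
  if (nrow(events) == 0L) return(list())
  ref <- reference_psd(rec, hyp)
  lapply(seq_len(nrow(events)), function(i) {
    ps <- tryCatch(event_psd(rec, events[i, ]), error = function(e) NULL)
    if (is.null(ps)) return(NULL)
    extract_peaks(normalize_spectrum(ps, ref), band = band)
  })
}

#' Cohort peak summary
#'
#' Per-mouse mean spectra and mean peak frequencies, and population
#' mean +/- SEM. Peaks are averaged per event then per mouse (the
#' per-mouse mean spectrum and its peaks are also reported).
#'
#' @param spectra_by_mouse named list; each element is the
#'   `event_spectra()` list of one mouse.
#' @return list with `per_mouse` (data.frame) and `population`
#'   (means and SEMs of peak frequencies).
#' @export
cohort_peak_summary <- function(spectra_by_mouse) {
  rows <- list()
  for (m in names(spectra_by_mouse)) {
    sp <- Filter(Negate(is.null), spectra_by_mouse[[m]])
    if (length(sp) == 0L) {
      warning("mouse ", m, " has no usable events; excluded")
      next
    }
    p1 <- vapply(sp, function(s) s$peak1_hz, numeric(1))
    p2 <- vapply(sp, function(s) s$peak2_hz, numeric(1))
    mean_spec <- Reduce(`+`, lapply(sp, function(s) s$power_pct)) / length(sp)
    mpk <- extract_peaks(list(freq = SPECTRUM_GRID, power_pct = mean_spec))
    rows[[m]] <- data.frame(
      mouse = m, n_events = length(sp),
      peak1_hz = mean(p1, na.rm = TRUE), peak2_hz = mean(p2, na.rm = TRUE),
      peak1_of_mean_spectrum = mpk$peak1_hz,
      peak2_of_mean_spectrum = mpk$peak2_hz
    )
  }
  per_mouse <- do.call(rbind, rows)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  population <- if (!is.null(per_mouse) && nrow(per_mouse) > 0L) {
    list(peak1_mean = mean(per_mouse$peak1_hz), peak1_sem = sem(per_mouse$peak1_hz),
         peak2_mean = mean(per_mouse$peak2_hz), peak2_sem = sem(per_mouse$peak2_hz))
  } else NULL
  list(per_mouse = per_mouse, population = population)
}
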