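#' @keywords internal
"_PACKAGE"

# Shared DSP primitives: Welch PSD with the estimator settings used
# throughout the package (2-s Hanning windows, 0.5-s overlap, zero-padded
# so the native grid is <= 0.1 Hz), and an FFT-based analytic envelope.

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hanning windows. Segments shorter than one full
#' window fall back to a single Hanning window of the segment length, so
#' short event segments (the common case for ~2-s discharges) are still
#' estimable. The FFT is zero-padded so the native frequency grid is at
#' most `grid_hz`.
#'
#' @param x numeric signal (microvolts).
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 2).
#' @param overlap_s overlap between successive windows in seconds
#'   (default 0.5, i.e. a 1.5-s hop at the default window).
#' @param grid_hz maximum spacing of the returned frequency grid (Hz).
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz), plus `n_segments`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap_s = 0.5, grid_hz = 0.1) {
  stopifnot(fs > 0, window_s > 0, overlap_s >= 0, overlap_s < window_s)
  n <- length(x)
  if (n < 2L) stop("signal too short for PSD estimation")
  win_n <- round(window_s * fs)
  hop <- round((window_s - overlap_s) * fs)
  if (n < win_n) {
    win_n <- n
    hop <- n
  }
  starts <- seq(1L, n - win_n + 1L, by = hop)
  w <- hanning_window(win_n)
  u <- sum(w^2)
  nfft <- welch_nfft(win_n, fs, grid_hz)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + win_n - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - win_n)))
    p <- Mod(X[1:(nfft %/% 2L + 1L)])^2
    acc <- acc + p
  }
  psd <- acc / length(starts) / (fs * u)
  # one-sided: double everything except DC and Nyquist
  psd[2:(length(psd) - 1L)] <- 2 * psd[2:(length(psd) - 1L)]
  freq <- (0:(nfft %/% 2L)) * fs / nfft
  list(freq = freq, psd = psd, n_segments = length(starts))
}

# next power of two large enough for both the window and the target grid
welch_nfft <- function(win_n, fs, grid_hz) {
  need <- max(win_n, ceiling(fs / grid_hz))
  2L^ceiling(log2(need))
}

hanning_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Per-epoch Welch PSDs for a whole recording
#'
#' Computes the Welch PSD of every scoring epoch in one vectorized pass
#' (segments gathered into matrices, chunked `mvfft`). Windows never span
#' epoch boundaries, so averaging PSD rows over any epoch subset equals a
#' Welch estimate over the concatenation of those epochs.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param epoch_len_s epoch length in seconds (default 10).
#' @inheritParams welch_psd
#' @return list with `freq`, `psd` (matrix, epochs x frequency bins) and
#'   `epoch_len_s`.
#' @export
epoch_psd_matrix <- function(x, fs, epoch_len_s = 10, window_s = 2,
                             overlap_s = 0.5, grid_hz = 0.1) {
  n <- length(x)
  ep_n <- round(epoch_len_s * fs)
  n_ep <- n %/% ep_n
  if (n_ep < 1L) stop("recording shorter than one epoch")
  win_n <- round(window_s * fs)
  hop <- round((window_s - overlap_s) * fs)
  offs <- seq(0L, ep_n - win_n, by = hop)  # within-epoch segment starts
  n_seg <- length(offs)
  w <- hanning_window(win_n)
  u <- sum(w^2)
  nfft <- welch_nfft(win_n, fs, grid_hz)
  half <- nfft %/% 2L + 1L

  seg_start <- rep((0:(n_ep - 1L)) * ep_n, each = n_seg) + rep(offs, n_ep)
  idx <- outer(1:win_n, seg_start, `+`)  # win_n x (n_seg*n_ep)
  segs <- matrix(x[idx], nrow = win_n) * w
  total_cols <- ncol(segs)
  out <- matrix(0, nrow = half, ncol = total_cols)
  chunk <- max(1L, floor(2^22 / nfft))
  pad <- matrix(0, nrow = nfft - win_n, ncol = chunk)
  for (c0 in seq(1L, total_cols, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, total_cols)
    block <- segs[, c0:c1, drop = FALSE]
    if (ncol(block) < chunk) pad <- matrix(0, nrow = nfft - win_n, ncol = ncol(block))
    X <- stats::mvfft(rbind(block, pad))
    out[, c0:c1] <- Mod(X[1:half, , drop = FALSE])^2
  }
  out <- out / (fs * u)
  out[2:(half - 1L), ] <- 2 * out[2:(half - 1L), ]
  # average segments within each epoch -> one PSD row per epoch
  grp <- rep(1:n_ep, each = n_seg)
  psd <- t(rowsum(t(out), grp) / n_seg)
  list(freq = (0:(nfft %/% 2L)) * fs / nfft, psd = t(psd),
       epoch_len_s = epoch_len_s)
}

#' Band power from a PSD
#'
#' Integrates a PSD over `[lo, hi)` Hz by the rectangle rule on the native
#' grid.
#' @param freq,psd frequency grid and PSD values (vector or matrix with
#'   frequencies along columns).
#' @param lo,hi band edges in Hz.
#' @export
band_power <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sel <- freq >= lo & freq < hi
  if (is.matrix(psd)) rowSums(psd[, sel, drop = FALSE]) * df
  else sum(psd[sel]) * df
}

#' Analytic envelope of a signal
#'
#' Magnitude of the analytic signal, computed by the FFT method in
#' overlapping chunks so day-long recordings do not require a single huge
#' transform.
#' @param x numeric signal.
#' @param chunk chunk length in samples (power of two).
#' @return numeric vector, same length as `x`.
#' @export
analytic_envelope <- function(x, chunk = 2L^19L) {
  n <- length(x)
  if (n <= chunk) return(Mod(analytic_chunk(x)))
  pad <- 2L^12L  # discard edges distorted by circularity
  env <- numeric(n)
  s <- 1L
  while (s <= n) {
    e <- min(s + chunk - 1L, n)
    s_ext <- max(1L, s - pad)
    e_ext <- min(n, e + pad)
    seg_env <- Mod(analytic_chunk(x[s_ext:e_ext]))
    env[s:e] <- seg_env[(s - s_ext + 1L):(s - s_ext + 1L + (e - s))]
    s <- e + 1L
  }
  env
}

analytic_chunk <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# ---- chunked FFT-domain zero-phase filtering -------------------------------
#
# Zero-phase IIR filtering (forward-backward) is equivalent to multiplying
# the spectrum by |H(w)|^2. Applying that response directly in the
# frequency domain, in overlapping chunks, costs two FFTs per pass no
# matter how many filter stages are stacked, which matters for day-long
# recordings.

# squared magnitude response of a digital filter (b, a) on a frequency grid
filter_mag_sq <- function(b, a, freq, fs) {
  w <- 2 * pi * freq / fs
  z <- exp(-1i * outer(w, seq_along(b) - 1L))
  num <- as.vector(z %*% b)
  z <- exp(-1i * outer(w, seq_along(a) - 1L))
  den <- as.vector(z %*% a)
  Mod(num / den)^2
}

# transfer functions are identical across chunks and across recordings of
# the same length/rate, so cache them package-wide
.tf_cache <- new.env(parent = emptyenv())

# apply a real, even transfer function tf(freq_hz) chunk-wise; analytic =
# TRUE additionally zeroes negative frequencies (x2 positive) so the
# result is the analytic signal of the filtered input (complex).
# cache_key, when given, memoizes the sampled transfer function.
fft_apply <- function(x, fs, tf_fun, analytic = FALSE, chunk = 2L^19L,
                      pad = 2L^13L, cache_key = NULL) {
  n <- length(x)
  # reflect-pad the recording edges so slow components stay continuous
  # across the (circular) chunk boundary
  npad <- min(pad, n - 1L)
  xx <- c(x[(npad + 1L):2L], x, x[(n - 1L):(n - npad)])
  off <- npad
  out <- if (analytic) complex(n) else numeric(n)
  tf_cache <- list()
  s <- 1L
  while (s <= n) {
    e <- min(s + chunk - 1L, n)
    s_ext <- s + off - pad
    e_ext <- e + off + pad
    s_ext <- max(1L, s_ext)
    e_ext <- min(length(xx), e_ext)
    m <- e_ext - s_ext + 1L
    key <- paste0(if (is.null(cache_key)) "" else cache_key, "|",
                  analytic, "|", fs, "|", m)
    if (!is.null(cache_key) && !is.null(.tf_cache[[key]])) {
      tf_cache[[key]] <- .tf_cache[[key]]
    }
    if (is.null(tf_cache[[key]])) {
      freq <- c(0:(m %/% 2L), -((m - m %/% 2L - 1L):1)) * fs / m
      tf <- tf_fun(abs(freq))
      if (analytic) {
        h <- numeric(m)
        if (m %% 2L == 0L) {
          h[c(1L, m %/% 2L + 1L)] <- 1
          h[2:(m %/% 2L)] <- 2
        } else {
          h[1L] <- 1
          h[2:((m + 1L) %/% 2L)] <- 2
        }
        tf <- tf * h
      }
      tf_cache[[key]] <- tf
      if (!is.null(cache_key)) .tf_cache[[key]] <- tf
    }
    y <- stats::fft(stats::fft(xx[s_ext:e_ext]) * tf_cache[[key]],
                    inverse = TRUE) / m
    if (!analytic) y <- Re(y)
    i0 <- s + off - s_ext + 1L
    out[s:e] <- y[i0:(i0 + (e - s))]
    s <- e + 1L
  }
  out
}

# zero-phase Butterworth chain (list of signal::butter objects) via FFT
fft_zero_phase <- function(x, fs, filters, cache_key = NULL) {
  fft_apply(x, fs, function(f) {
    tf <- rep(1, length(f))
    for (ft in filters) tf <- tf * filter_mag_sq(ft$b, ft$a, f, fs)
    tf
  }, cache_key = cache_key)
}

# band-passed analytic signal in one pass (zero-phase band response)
fft_band_analytic <- function(x, fs, band, order = 4) {
  bp <- signal::butter(order, band / (fs / 2), type = "pass")
  fft_apply(x, fs, function(f) filter_mag_sq(bp$b, bp$a, f, fs),
            analytic = TRUE,
            cache_key = paste0("band", band[1], "-", band[2], "o", order))
}

# synthesize stationary Gaussian noise with power spectrum tf(f)^2 (i.e.
# the spectrum a zero-phase tf pass would give white noise), directly in
# the frequency domain, chunk-wise with an equal-power crossfade so the
# result is seamless; ~half the FFT cost of filtering white noise
spectral_noise <- function(n, fs, tf_fun, cache_key = NULL,
                           chunk = 2L^19L, fade = 2L^12L) {
  out <- numeric(n)
  pos <- 1L
  prev_tail <- NULL
  w_up <- sin(pi / 2 * (seq_len(fade) - 0.5) / fade)  # equal-power ramp
  while (pos <= n) {
    m <- chunk
    key <- paste0("synth|", if (is.null(cache_key)) "" else cache_key,
                  "|", fs, "|", m)
    tf <- .tf_cache[[key]]
    if (is.null(tf)) {
      freq <- c(0:(m %/% 2L), -((m - m %/% 2L - 1L):1)) * fs / m
      tf <- tf_fun(abs(freq))
      if (!is.null(cache_key)) .tf_cache[[key]] <- tf
    }
    half <- m %/% 2L
    re <- stats::rnorm(half + 1L)
    im <- stats::rnorm(half + 1L)
    im[c(1L, half + 1L)] <- 0
    Z <- complex(real = c(re, re[half:2L]),
                 imaginary = c(im, -im[half:2L]))
    y <- Re(stats::fft(Z * tf, inverse = TRUE)) / sqrt(m)
    if (!is.null(prev_tail)) {
      y[seq_len(fade)] <- y[seq_len(fade)] * w_up +
        prev_tail * rev(w_up)
    }
    take <- min(m - fade, n - pos + 1L)
    out[pos:(pos + take - 1L)] <- y[seq_len(take)]
    prev_tail <- y[(m - fade + 1L):m]
    pos <- pos + take
  }
  out
}

#' Centered moving average
#' @param x numeric vector.
#' @param k window length in samples (forced odd).
#' @keywords internal
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (k <= 1L || n < k) return(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  out <- numeric(n)
  core <- (half + 1L):(n - half)
  out[core] <- (cs[core + half + 1L] - cs[core - half]) / k
  # shrinking windows at the edges
  for (i in seq_len(half)) {
    out[i] <- cs[i + half + 1L] / (i + half)
    out[n - i + 1L] <- (cs[n + 1L] - cs[n - i - half + 1L]) / (i + half)
  }
  out
}

#' Zeitgeber time of a moment within a recording
#'
#' @param t_s seconds from recording start.
#' @param start_zt ZT (hours since lights-on) of sample 0.
#' @return ZT hours in `[0, 24)`.
#' @export
zt_at <- function(t_s, start_zt) (start_zt + t_s / 3600) %% 24
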