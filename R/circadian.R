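# Circadian statistics of discharge occurrence: hourly ZT histogram with
# per-minute-in-SWS rates, Rayleigh uniformity test, and 24-h cosinor.

#' Hourly ZT histogram and SWS-normalized rates
#'
#' Bins event onsets into the 24 hourly ZT bins `[h, h+1)` and divides by
#' the minutes of SWS the hypnogram spends in each bin. Hours with no SWS
#' time get `NA` rates.
#'
#' @param events an `event_table` with `onset_zt_h` filled.
#' @param hyp a `hypnogram`.
#' @return data.frame with `zt_hour` (0-23), `count`, `sws_min`,
#'   `rate_per_sws_min`.
#' @export
hourly_histogram <- function(events, hyp) {
  zt_bins <- 0:23
  counts <- vapply(zt_bins, function(h) {
    sum(events$onset_zt_h >= h & events$onset_zt_h < h + 1)
  }, numeric(1))
  ep_zt <- epoch_zt(hyp)
  sws_min <- vapply(zt_bins, function(h) {
    sum(ep_zt >= h & ep_zt < h + 1 & hyp$labels == "SWS") *
      hyp$epoch_len_s / 60
  }, numeric(1))
  data.frame(
    zt_hour = zt_bins,
    count = counts,
    sws_min = sws_min,
    rate_per_sws_min = ifelse(sws_min > 0, counts / sws_min, NA_real_)
  )
}

#' Rayleigh test of circular uniformity
#'
#' Event ZTs are mapped to phases `theta = 2*pi*zt/24`; the mean
#' resultant length `R`, `Z = n R^2`, and the small-sample-corrected
#' p-value approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))` (Zar 1999) are
#' returned, with the mean phase in radians and ZT hours.
#'
#' @param zt_h event ZT hours (n >= 2).
#' @return list of class `rayleigh_result` with `n`, `R`, `Z`, `p`,
#'   `mean_phase_rad`, `mean_phase_zt`.
#' @export
rayleigh_test <- function(zt_h) {
  n <- length(zt_h)
  if (n < 2L) stop("Rayleigh test requires at least 2 events")
  theta <- 2 * pi * (zt_h %% 24) / 24
  C <- sum(cos(theta)); S <- sum(sin(theta))
  Rn <- sqrt(C^2 + S^2)
  R <- Rn / n
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  p <- min(1, max(p, 0))
  mp <- atan2(S, C) %% (2 * pi)
  structure(list(n = n, R = R, Z = Z, p = p, mean_phase_rad = mp,
                 mean_phase_zt = mp * 24 / (2 * pi)),
            class = "rayleigh_result")
}

#' 24-h cosinor fit
#'
#' Linear least squares of `y = M + bc*cos(wt) + bs*sin(wt)` with
#' `w = 2*pi/period`. Amplitude `A = sqrt(bc^2 + bs^2)`, acrophase
#' `phi = atan2(bs, bc) * period/(2*pi) mod period` (the time of the
#' fitted maximum), plus the zero-amplitude F test on (2, n-3) df.
#'
#' @param t_h time points in hours (>= 4 distinct values mod period).
#' @param y response (e.g. hourly event counts).
#' @param period_h period in hours (fixed, default 24).
#' @return list of class `cosinor_result` with `mesor`, `amplitude`,
#'   `acrophase_h`, `F`, `p`, `fitted`.
#' @export
cosinor_fit <- function(t_h, y, period_h = 24) {
  if (length(t_h) != length(y)) stop("t_h and y lengths differ")
  tt <- t_h %% period_h
  if (length(unique(round(tt, 9))) < 4L) {
    stop("cosinor needs at least 4 distinct time points within the period")
  }
  w <- 2 * pi / period_h
  cw <- cos(w * t_h); sw <- sin(w * t_h)
  fit <- stats::lm(y ~ cw + sw)
  b <- stats::coef(fit)
  amp <- sqrt(b[["cw"]]^2 + b[["sw"]]^2)
  phi <- (atan2(b[["sw"]], b[["cw"]]) * period_h / (2 * pi)) %% period_h
  n <- length(y)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  Fst <- if (rss1 > 0) ((rss0 - rss1) / 2) / (rss1 / (n - 3)) else Inf
  p <- stats::pf(Fst, 2, n - 3, lower.tail = FALSE)
  structure(list(mesor = b[[1L]], amplitude = amp, acrophase_h = phi,
                 F = Fst, p = p, fitted = stats::fitted(fit)),
            class = "cosinor_result")
}

#' Cosinor fit of hourly event counts
#'
#' Bins events into hourly ZT bins (the presentation used for circadian
#' discharge profiles) and fits the 24-h cosinor to the bin centers.
#'
#' @param events an `event_table` with `onset_zt_h`.
#' @param hyp hypnogram (defines the bins via `hourly_histogram()`).
#' @return a `cosinor_result`.
#' @export
cosinor_from_events <- function(events, hyp) {
  h <- hourly_histogram(events, hyp)
  cosinor_fit(h$zt_hour + 0.5, h$count)
}
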