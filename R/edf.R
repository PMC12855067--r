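# EDF (European Data Format) reader/writer. EDF stores 16-bit samples in
# fixed-duration data records; a JSON sidecar (<path>.json) carries the
# Zeitgeber anchor (start_zt, light_period_h) and exact sample count,
# since EDF's own start time is wall-clock and records are padded to whole
# seconds.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too long: ", s)
  formatC(s, width = -width, flag = " ")
}

fmt8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), format = "g", digits = d)
    if (nchar(s) <= 8L) return(edf_field(s, 8L))
  }
  stop("cannot format ", x, " in 8 characters")
}

#' Write a recording to EDF
#'
#' Samples are quantized to 16 bits over a symmetric physical range chosen
#' per channel (the maximum absolute sample value), so the quantization
#' error is bounded by range/2^15. The final data record is zero-padded to
#' a whole second; the exact sample count, `start_zt` and `light_period_h`
#' travel in a JSON sidecar at `<path>.json`.
#'
#' @param rec a `signal_recording` with finite samples and integer `fs`.
#' @param path output file path.
#' @param physical_max optional physical range override (microvolts),
#'   recycled over channels.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_max = NULL) {
  if (length(rec$channels) == 0L) stop("recording has no channels")
  if (rec$fs != round(rec$fs)) stop("write_edf requires an integer sampling rate")
  for (ch in rec$channels) {
    if (any(!is.finite(ch$samples))) stop("non-finite samples in channel ", ch$name)
  }
  ns <- length(rec$channels)
  n <- n_samples(rec)
  spr <- as.integer(rec$fs)             # 1-s records
  n_rec <- as.integer(ceiling(n / spr))
  pmax <- vapply(rec$channels, function(ch) max(abs(ch$samples), 1e-6), numeric(1))
  if (!is.null(physical_max)) pmax <- rep_len(physical_max, ns)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8), edf_field("X X X X", 80), edf_field("Startdate X X X X", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256L * (1L + ns), 8), edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1L, 8), edf_field(ns, 4)
  )
  labels <- vapply(rec$channels, function(ch) ch$name, character(1))
  sig_hdr <- paste0(
    paste0(vapply(labels, edf_field, character(1), width = 16L), collapse = ""),
    paste0(rep(edf_field("", 80), ns), collapse = ""),
    paste0(rep(edf_field("uV", 8), ns), collapse = ""),
    paste0(vapply(-pmax, fmt8, character(1)), collapse = ""),
    paste0(vapply(pmax, fmt8, character(1)), collapse = ""),
    paste0(rep(edf_field("-32767", 8), ns), collapse = ""),
    paste0(rep(edf_field("32767", 8), ns), collapse = ""),
    paste0(rep(edf_field("", 80), ns), collapse = ""),
    paste0(rep(edf_field(spr, 8), ns), collapse = ""),
    paste0(rep(edf_field("", 32), ns), collapse = "")
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  dig <- matrix(0L, nrow = n_rec * spr, ncol = ns)
  for (j in seq_len(ns)) {
    x <- rec$channels[[j]]$samples
    d <- as.integer(round(x / pmax[j] * 32767))
    d[d > 32767L] <- 32767L
    d[d < -32767L] <- -32767L
    dig[seq_len(n), j] <- d
  }
  # interleave: per record, all samples of ch1, then ch2, ...
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(dig[rows, ]), con, size = 2L, endian = "little")
  }

  jsonlite::write_json(
    list(start_zt = rec$start_zt, light_period_h = rec$light_period_h,
         n_samples = n,
         roles = stats::setNames(
           as.list(vapply(rec$channels, function(ch) ch$role, character(1))),
           labels)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EDF recording
#'
#' Channel roles come from the JSON sidecar when present, otherwise from a
#' label-mapping table (labels containing "emg" map to EMG, "front" to
#' EEG_frontal, "pariet" to EEG_parietal, a bare "eeg" to EEG_frontal).
#' The file must contain at least one EEG and one EMG channel and all
#' channels must share one sampling rate.
#'
#' @param path EDF file path.
#' @return a `signal_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L) {
    stop("truncated EDF header at byte ", nchar(hdr, type = "bytes"))
  }
  sub8 <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_rec <- as.integer(sub8(hdr, 237, 8))
  rec_dur <- as.numeric(sub8(hdr, 245, 8))
  ns <- as.integer(sub8(hdr, 253, 4))
  sig <- readChar(con, 256L * ns, useBytes = TRUE)
  # signal header is field-major: ns labels, then ns transducers, ...
  take <- function(offset, width) {
    vapply(seq_len(ns) - 1L, function(i)
      trimws(substr(sig, offset + i * width + 1L, offset + (i + 1L) * width)),
      character(1))
  }
  off <- 0L
  labels <- take(off, 16L); off <- off + 16L * ns
  off <- off + 80L * ns  # transducer
  off <- off + 8L * ns   # physical dimension
  pmin <- as.numeric(take(off, 8L)); off <- off + 8L * ns
  pmax <- as.numeric(take(off, 8L)); off <- off + 8L * ns
  dmin <- as.numeric(take(off, 8L)); off <- off + 8L * ns
  dmax <- as.numeric(take(off, 8L)); off <- off + 8L * ns
  off <- off + 80L * ns  # prefilter
  spr <- as.integer(take(off, 8L))

  if (length(unique(spr / rec_dur)) != 1L) {
    stop("channels have inconsistent sampling rates")
  }
  fs <- spr[1L] / rec_dur

  per_rec <- sum(spr)
  raw <- readBin(con, integer(), n = n_rec * per_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * per_rec) {
    stop("truncated EDF data at byte ",
         256L * (1L + ns) + 2L * length(raw))
  }
  arr <- matrix(raw, nrow = per_rec, ncol = n_rec)
  ch_rows <- split(seq_len(per_rec), rep(seq_len(ns), times = spr))

  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  n_keep <- if (!is.null(meta)) meta$n_samples else n_rec * spr[1L]

  roles <- character(ns)
  for (j in seq_len(ns)) {
    roles[j] <- if (!is.null(meta) && !is.null(meta$roles[[labels[j]]])) {
      meta$roles[[labels[j]]]
    } else {
      infer_channel_role(labels[j])
    }
  }
  if (any(is.na(roles))) {
    stop("cannot infer a role for channel label(s): ",
         paste(labels[is.na(roles)], collapse = ", "))
  }
  if (!any(grepl("^EEG", roles)) || !any(roles == "EMG")) {
    stop("role mapping requires at least one EEG and one EMG channel; got ",
         paste(roles, collapse = ", "))
  }

  channels <- vector("list", ns)
  for (j in seq_len(ns)) {
    d <- as.numeric(arr[ch_rows[[j]], ])
    x <- (d - dmin[j]) * (pmax[j] - pmin[j]) / (dmax[j] - dmin[j]) + pmin[j]
    channels[[j]] <- list(name = labels[j], role = roles[j],
                          samples = x[seq_len(n_keep)])
  }
  signal_recording(
    channels, fs = fs,
    start_zt = if (!is.null(meta)) meta$start_zt else 0,
    light_period_h = if (!is.null(meta)) meta$light_period_h else 12
  )
}
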