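# EventTable: detected or ground-truth SWD intervals. Intervals are
# half-open [onset_s, offset_s) in seconds from recording start.

EVENT_PROVENANCE <- c("detected", "ground_truth", "curated")

#' Construct an event table
#'
#' @param onset_s,offset_s event boundaries in seconds (half-open).
#' @param channel channel name the event was detected on.
#' @param state attributed vigilance state (state of the onset epoch), or
#'   `NA` before attribution.
#' @param onset_zt_h ZT hours of onset, or `NA` before attribution.
#' @param provenance `"detected"`, `"ground_truth"` or `"curated"`.
#' @param n_cycles,peak_amplitude_ratio optional detection metrics.
#' @return data.frame of class `event_table`, sorted by onset.
#' @export
event_table <- function(onset_s = numeric(0), offset_s = numeric(0),
                        channel = character(0), state = NA_character_,
                        onset_zt_h = NA_real_, provenance = "detected",
                        n_cycles = NA_integer_,
                        peak_amplitude_ratio = NA_real_) {
  n <- length(onset_s)
  df <- data.frame(
    onset_s = as.numeric(onset_s),
    offset_s = as.numeric(offset_s),
    channel = rep_len(as.character(channel), n),
    state = rep_len(as.character(state), n),
    onset_zt_h = rep_len(as.numeric(onset_zt_h), n),
    provenance = rep_len(as.character(provenance), n),
    n_cycles = rep_len(as.integer(n_cycles), n),
    peak_amplitude_ratio = rep_len(as.numeric(peak_amplitude_ratio), n),
    stringsAsFactors = FALSE
  )
  validate_event_table(df)
}

validate_event_table <- function(df) {
  if (nrow(df) > 0L) {
    if (any(!is.finite(df$onset_s)) || any(!is.finite(df$offset_s))) {
      stop("event boundaries must be finite")
    }
    if (any(df$onset_s >= df$offset_s)) {
      i <- which(df$onset_s >= df$offset_s)[1L]
      stop("event ", i, " has onset >= offset")
    }
    bad <- setdiff(unique(df$provenance), EVENT_PROVENANCE)
    if (length(bad) > 0L) stop("unknown provenance: ", paste(bad, collapse = ", "))
    df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
    rownames(df) <- NULL
    # no two events on the same channel may overlap
    for (ch in unique(df$channel)) {
      sub <- df[df$channel == ch, , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$onset_s[-1L] < sub$offset_s[-nrow(sub)])) {
        stop("overlapping events on channel ", ch)
      }
    }
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d event(s)\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Event durations in seconds
#' @param events an `event_table`.
#' @export
event_durations <- function(events) events$offset_s - events$onset_s

#' Read an event table CSV
#'
#' Columns `onset_s,offset_s,channel,state,onset_zt_h,provenance` (plus
#' optional detection metrics). Rows are sorted by onset on read.
#' @param path file path.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "channel", "state", "onset_zt_h", "provenance")
  if (!all(need %in% names(df))) {
    stop("event CSV must have columns ", paste(need, collapse = ", "))
  }
  event_table(df$onset_s, df$offset_s, df$channel, df$state, df$onset_zt_h,
              df$provenance,
              n_cycles = if ("n_cycles" %in% names(df)) df$n_cycles else NA_integer_,
              peak_amplitude_ratio = if ("peak_amplitude_ratio" %in% names(df))
                df$peak_amplitude_ratio else NA_real_)
}

#' Write an event table CSV
#' @param events an `event_table`.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df <- df[order(df$onset_s, df$offset_s), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
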