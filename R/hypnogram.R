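# Hypnogram: one vigilance-state label per 10-s scoring epoch.

VIGILANCE_STATES <- c("WAKE", "SWS", "REM", "ARTIFACT")

#' Construct a hypnogram
#'
#' @param labels character vector over `WAKE`, `SWS`, `REM`, `ARTIFACT`,
#'   one per epoch.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @param start_zt ZT hours of the first epoch's start.
#' @param original optional shadow copy of the labels before artifact
#'   tagging (kept so tagging is auditable).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len_s = 10, start_zt = 0, original = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), VIGILANCE_STATES)
  if (length(bad) > 0L) {
    stop("unknown vigilance state(s): ", paste(bad, collapse = ", "),
         " (alphabet is WAKE/SWS/REM/ARTIFACT)")
  }
  structure(
    list(labels = labels, epoch_len_s = epoch_len_s, start_zt = start_zt,
         original = original),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = VIGILANCE_STATES))
  cat(sprintf("<hypnogram> %d epochs x %g s, start ZT %.2f h\n",
              length(x$labels), x$epoch_len_s, x$start_zt))
  print(tab)
  invisible(x)
}

#' Number of epochs
#' @param hyp a `hypnogram`.
#' @export
n_epochs <- function(hyp) length(hyp$labels)

#' ZT hours at each epoch start
#' @param hyp a `hypnogram`.
#' @export
epoch_zt <- function(hyp) {
  zt_at((seq_len(n_epochs(hyp)) - 1L) * hyp$epoch_len_s, hyp$start_zt)
}

#' Epoch index containing a time point
#'
#' Epoch `e` (0-based) covers the half-open interval
#' `[e*epoch_len_s, (e+1)*epoch_len_s)`.
#' @param hyp a `hypnogram`.
#' @param t_s seconds from recording start.
#' @return 1-based epoch index (vectorized).
#' @export
epoch_of <- function(hyp, t_s) pmin(floor(t_s / hyp$epoch_len_s) + 1L, n_epochs(hyp))

#' Read a hypnogram CSV
#'
#' Expects a header `epoch_index,zt_start_h,state` with states in the
#' WAKE/SWS/REM/ARTIFACT alphabet. A header-only file yields a zero-epoch
#' hypnogram with a warning.
#'
#' @param path file path.
#' @param epoch_len_s epoch length in seconds (default 10).
#' @return a `hypnogram`.
#' @export
read_hypnogram <- function(path, epoch_len_s = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_start_h", "state")
  if (!all(need %in% names(df))) {
    stop("hypnogram CSV must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("hypnogram file has no epochs")
    return(hypnogram(character(0), epoch_len_s = epoch_len_s))
  }
  bad <- which(!df$state %in% VIGILANCE_STATES)
  if (length(bad) > 0L) {
    stop("unknown state '", df$state[bad[1L]], "' at row ", bad[1L],
         " (alphabet is WAKE/SWS/REM/ARTIFACT)")
  }
  df <- df[order(df$epoch_index), , drop = FALSE]
  hypnogram(df$state, epoch_len_s = epoch_len_s, start_zt = df$zt_start_h[1L] %% 24)
}

#' Write a hypnogram CSV
#' @param hyp a `hypnogram`.
#' @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(
    epoch_index = seq_len(n_epochs(hyp)) - 1L,
    zt_start_h = round(epoch_zt(hyp), 6),
    state = hyp$labels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hours spent in a state (artifact-free)
#' @param hyp a `hypnogram`.
#' @param state a vigilance state.
#' @export
hours_in_state <- function(hyp, state) {
  sum(hyp$labels == state) * hyp$epoch_len_s / 3600
}
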