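# Sleep architecture (time in state, bouts, transitions, fragmentation)
# and SWD-sleep interaction statistics (state attribution, conditional
# transition probabilities, fragmentation correlation).

TRANSITION_PAIRS <- c("WAKE->SWS", "SWS->WAKE", "SWS->REM",
                      "REM->WAKE", "REM->SWS", "WAKE->REM")

# maximal same-label runs over artifact-free epochs; ARTIFACT breaks runs
# without creating transitions
state_runs <- function(labels) {
  idx <- which(labels != "ARTIFACT")
  if (length(idx) == 0L) {
    return(data.frame(state = character(0), length = integer(0),
                      segment = integer(0)))
  }
  seg <- cumsum(c(1L, diff(idx) != 1L))
  out <- lapply(split(idx, seg), function(ii) {
    r <- rle(labels[ii])
    data.frame(state = r$values, length = r$lengths)
  })
  segs <- rep(seq_along(out), vapply(out, nrow, integer(1)))
  res <- do.call(rbind, out)
  res$segment <- segs
  rownames(res) <- NULL
  res
}

#' Sleep architecture summary
#'
#' Fractions of artifact-free time per state, bout counts and mean bout
#' durations (a bout is a maximal same-state run of epochs), total
#' transitions and transitions per hour (fragmentation index), and the
#' relative frequencies of the six ordered transition pairs. ARTIFACT
#' epochs are excluded from all denominators and break runs without
#' contributing transitions.
#'
#' @param hyp a `hypnogram` with at least 2 artifact-free epochs.
#' @return list of class `architecture_summary`.
#' @export
summarize_architecture <- function(hyp) {
  labels <- hyp$labels
  if (sum(labels != "ARTIFACT") < 2L) {
    stop("fewer than 2 analyzable (artifact-free) epochs")
  }
  runs <- state_runs(labels)
  st <- c("WAKE", "SWS", "REM")
  n_free <- sum(labels != "ARTIFACT")
  frac <- vapply(st, function(s) sum(labels == s) / n_free, numeric(1))
  bout_count <- vapply(st, function(s) sum(runs$state == s), numeric(1))
  bout_mean_s <- vapply(st, function(s) {
    if (bout_count[[s]] == 0) return(NA_real_)
    mean(runs$length[runs$state == s]) * hyp$epoch_len_s
  }, numeric(1))
  # transitions: adjacent label changes within artifact-free segments
  pair_counts <- stats::setNames(numeric(length(TRANSITION_PAIRS)),
                                 TRANSITION_PAIRS)
  n_trans <- 0L
  for (g in split(runs, runs$segment)) {
    if (nrow(g) > 1L) {
      from <- g$state[-nrow(g)]
      to <- g$state[-1L]
      n_trans <- n_trans + length(from)
      key <- paste0(from, "->", to)
      tt <- table(key)
      pair_counts[names(tt)] <- pair_counts[names(tt)] + as.numeric(tt)
    }
  }
  n_segments <- length(unique(runs$segment))
  stopifnot(n_trans == nrow(runs) - n_segments)  # run-length identity
  hours_free <- n_free * hyp$epoch_len_s / 3600
  structure(list(
    state_fraction = frac,
    bout_count = bout_count,
    bout_mean_s = bout_mean_s,
    n_transitions = n_trans,
    transitions_per_h = n_trans / hours_free,
    pair_freq = if (n_trans > 0L) pair_counts / n_trans else pair_counts,
    hours_analyzable = hours_free
  ), class = "architecture_summary")
}

#' Attribute events to vigilance states
#'
#' Each event takes the state of its onset epoch. Events with onsets in
#' ARTIFACT epochs are labeled ARTIFACT and excluded from the state
#' shares (reported separately). Rates are events per hour spent in each
#' state.
#'
#' @param events an `event_table` within the hypnogram span.
#' @param hyp a `hypnogram`.
#' @return list with the updated `events`, `state_counts`,
#'   `state_shares_pct` (over non-ARTIFACT events), `rate_per_h`,
#'   `n_artifact_events`, `mean_duration_s` per state.
#' @export
attribute_events <- function(events, hyp) {
  st <- c("SWS", "WAKE", "REM")
  if (nrow(events) > 0L) {
    events$state <- hyp$labels[epoch_of(hyp, events$onset_s)]
    events$onset_zt_h <- zt_at(events$onset_s, hyp$start_zt)
  }
  ok <- events$state != "ARTIFACT"
  counts <- vapply(st, function(s) sum(events$state[ok] == s), numeric(1))
  hours <- vapply(st, function(s) hours_in_state(hyp, s), numeric(1))
  shares <- if (sum(counts) > 0) 100 * counts / sum(counts) else counts
  mean_dur <- vapply(st, function(s) {
    d <- event_durations(events)[ok & events$state == s]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, numeric(1))
  list(events = events,
       state_counts = counts,
       state_shares_pct = shares,
       rate_per_h = ifelse(hours > 0, counts / hours, NA_real_),
       mean_duration_s = mean_dur,
       n_artifact_events = sum(!ok))
}

#' Conditional transition probabilities around SWD epochs
#'
#' An epoch "contains" an SWD when any event overlaps it (default;
#' `containment = "onset"` restricts to onset-containment). A transition
#' "follows" epoch e when the next epoch's label differs; only
#' artifact-free epoch pairs count. Reports P(transition | SWD epoch),
#' P(transition | SWD-free epoch), their ratio with a seeded bootstrap
#' CI, and the per-pair conditional breakdown.
#'
#' @param events an `event_table`.
#' @param hyp a `hypnogram`.
#' @param containment `"overlap"` or `"onset"`.
#' @param n_boot bootstrap resamples for the ratio CI (0 disables).
#' @param seed bootstrap seed.
#' @return list of class `interaction_summary`.
#' @export
conditional_transitions <- function(events, hyp, containment = "overlap",
                                    n_boot = 1000, seed = 1) {
  n <- n_epochs(hyp)
  len <- hyp$epoch_len_s
  has_swd <- rep(FALSE, n)
  if (nrow(events) > 0L) {
    if (containment == "overlap") {
      first <- pmax(1L, floor(events$onset_s / len) + 1L)
      last <- pmin(n, ceiling(events$offset_s / len - 1e-9))
      for (i in seq_len(nrow(events))) {
        has_swd[first[i]:last[i]] <- TRUE
      }
    } else {
      has_swd[epoch_of(hyp, events$onset_s)] <- TRUE
    }
  }
  lab <- hyp$labels
  usable <- which(lab[-n] != "ARTIFACT" & lab[-1L] != "ARTIFACT")
  trans <- lab[usable] != lab[usable + 1L]
  cond <- has_swd[usable]
  p_swd <- if (any(cond)) mean(trans[cond]) else NA_real_
  p_free <- if (any(!cond)) mean(trans[!cond]) else NA_real_
  ratio <- if (!is.na(p_swd) && !is.na(p_free) && p_free > 0) {
    p_swd / p_free
  } else NA_real_

  pair_prob <- function(sel) {
    out <- stats::setNames(numeric(length(TRANSITION_PAIRS)), TRANSITION_PAIRS)
    key <- paste0(lab[usable[sel]], "->", lab[usable[sel] + 1L])
    key <- key[trans[sel]]
    if (length(key) > 0L) {
      tt <- table(key) / sum(sel)
      out[names(tt)] <- as.numeric(tt)
    }
    out
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && !is.na(ratio)) {
    set.seed(seed)
    idx_swd <- which(cond); idx_free <- which(!cond)
    bs <- replicate(n_boot, {
      a <- mean(trans[sample(idx_swd, replace = TRUE)])
      b <- mean(trans[sample(idx_free, replace = TRUE)])
      if (b > 0) a / b else NA_real_
    })
    ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  structure(list(
    p_transition_swd = p_swd,
    p_transition_free = p_free,
    ratio = ratio,
    ratio_ci95 = ci,
    n_swd_epochs = sum(cond),
    n_free_epochs = sum(!cond),
    pair_prob_swd = pair_prob(cond),
    pair_prob_free = pair_prob(!cond)
  ), class = "interaction_summary")
}

#' Fragmentation-discharge correlation across animals
#'
#' Pearson correlation (two-sided t test on n-2 df) and least-squares
#' slope between per-animal transition counts and SWD counts.
#'
#' @param transitions,swd_counts numeric vectors, one value per animal
#'   (n >= 3).
#' @return list with `r`, `p`, `slope`, `n`.
#' @export
correlate_fragmentation <- function(transitions, swd_counts) {
  n <- length(transitions)
  if (n < 3L || n != length(swd_counts)) {
    stop("need matched vectors for at least 3 animals")
  }
  if (stats::sd(transitions) == 0 || stats::sd(swd_counts) == 0) {
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_, n = n,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(swd_counts, transitions)
  slope <- stats::coef(stats::lm(transitions ~ swd_counts))[[2L]]
  list(r = unname(ct$estimate), p = ct$p.value, slope = slope, n = n,
       degenerate = FALSE)
}
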