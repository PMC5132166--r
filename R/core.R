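#' @importFrom stats rlnorm rgamma runif rbinom sd cor aggregate pf pnorm
#'   plogis qnorm rnorm complete.cases setNames binomial quantile
#' @importFrom utils read.csv write.csv head tail
NULL

# Channels are always the two labels "A" and "B".
.CHANNELS <- c("A", "B")

#' Construct a whistle event table
#'
#' One row per whistle. Onset/offset are in seconds on a shared dialog
#' clock; amplitudes are arbitrary linear units (the absolute scale of a
#' recording chain carries no meaning, only ratios and differences do).
#'
#' @param channel character vector of "A"/"B".
#' @param onset,offset numeric vectors, seconds, `offset > onset`.
#' @param peak_amp,mean_amp non-negative numeric vectors.
#' @return a `data.frame` of class `whistle_events`, sorted by onset with
#'   exactly simultaneous onsets ordered A before B.
#' @export
whistle_events <- function(channel = character(), onset = numeric(),
                           offset = numeric(), peak_amp = numeric(),
                           mean_amp = numeric()) {
  n <- length(onset)
  stopifnot(length(channel) == n, length(offset) == n,
            length(peak_amp) == n, length(mean_amp) == n)
  channel <- as.character(channel)
  if (n > 0) {
    if (!all(channel %in% .CHANNELS))
      stop("channel must be 'A' or 'B'")
    if (any(offset <= onset))
      stop("every event needs offset > onset")
    if (any(peak_amp < 0) || any(mean_amp < 0))
      stop("amplitudes must be >= 0")
  }
  ev <- data.frame(channel = channel, onset = as.numeric(onset),
                   offset = as.numeric(offset),
                   peak_amp = as.numeric(peak_amp),
                   mean_amp = as.numeric(mean_amp),
                   stringsAsFactors = FALSE)
  ev <- sort_events(ev)
  class(ev) <- c("whistle_events", "data.frame")
  ev
}

# Sort strictly by onset; exactly simultaneous onsets are ordered by
# channel label (A before B) so the event order is deterministic. Near
# ties keep their onset order, which keeps the sorted sequence consistent
# with onset-value comparisons everywhere downstream.
sort_events <- function(ev) {
  if (nrow(ev) < 2) return(ev)
  o <- order(ev$onset, match(ev$channel, .CHANNELS))
  ev <- ev[o, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Construct a dialog round
#'
#' A dialog is one recorded round between two whistlers on isolated
#' channels A and B, with the end-of-round claim ("I won") and the
#' end-of-experiment fairness judgment attached as metadata. Claims are
#' experimenter-recorded outcomes, never inferred from the audio.
#'
#' @param events a [whistle_events()] table (may be empty).
#' @param pair_id identifier of the whistler pair.
#' @param round_index integer >= 0, position of this round in the session.
#' @param condition `"competitive"` or `"non_competitive"`.
#' @param round_duration round length in seconds; all events must lie in
#'   `[0, round_duration]`.
#' @param claim_A,claim_B did the channel whistle at round end to claim the
#'   reward (logical; `NA` allowed for non-competitive rounds).
#' @param fair_A,fair_B optional end-of-experiment fairness judgments.
#' @return an object of class `dialog`.
#' @export
dialog <- function(events, pair_id = "pair1", round_index = 0L,
                   condition = c("competitive", "non_competitive"),
                   round_duration = 60,
                   claim_A = NA, claim_B = NA,
                   fair_A = NA, fair_B = NA) {
  condition <- match.arg(condition)
  if (!inherits(events, "whistle_events"))
    events <- whistle_events(events$channel, events$onset, events$offset,
                             events$peak_amp, events$mean_amp)
  stopifnot(round_duration > 0)
  if (nrow(events) > 0 &&
      (min(events$onset) < 0 || max(events$offset) > round_duration + 1e-9))
    stop("events must lie within [0, round_duration]")
  structure(list(pair_id = pair_id, round_index = as.integer(round_index),
                 condition = condition,
                 round_duration = as.numeric(round_duration),
                 events = events,
                 claim_A = claim_A, claim_B = claim_B,
                 fair_A = fair_A, fair_B = fair_B),
            class = "dialog")
}

#' @export
print.dialog <- function(x, ...) {
  cat(sprintf("<dialog> pair %s round %d (%s): %d events on A, %d on B, %.3g s\n",
              x$pair_id, x$round_index, x$condition,
              sum(x$events$channel == "A"), sum(x$events$channel == "B"),
              x$round_duration))
  invisible(x)
}

# Integer utterance index per event. An utterance is a maximal run of
# same-channel events in the onset-sorted order: any partner onset falling
# between two same-channel onsets (or after the last one) starts a new run,
# which is exactly the onset-based interruption rule.
utterance_index <- function(events) {
  n <- nrow(events)
  if (n == 0) return(integer(0))
  ch <- events$channel
  cumsum(c(TRUE, ch[-1] != ch[-n]))
}

#' Segment a dialog into utterances
#'
#' An utterance is a sequence of one channel's whistles without partner
#' interruption: a partner onset strictly between two same-channel onsets
#' terminates the current utterance, and so does a partner whistle that
#' starts during the tail of the last whistle of a run. Every event belongs
#' to exactly one utterance and concatenating utterances in order
#' reproduces the event sequence.
#'
#' @param dlg a [dialog()].
#' @return list of `utterance` objects, each a list with `channel` and an
#'   `events` data.frame; empty list for an event-less dialog.
#' @export
segment_utterances <- function(dlg) {
  ev <- dlg$events
  idx <- utterance_index(ev)
  if (length(idx) == 0) return(list())
  unname(lapply(split(seq_len(nrow(ev)), idx), function(i) {
    u <- list(channel = ev$channel[i[1]],
              events = `rownames<-`(ev[i, , drop = FALSE], NULL))
    class(u) <- "utterance"
    u
  }))
}

#' Turn-taking gaps of a dialog
#'
#' For each channel-switch transition between consecutive utterances, the
#' pause from the previous speaker's last offset to the responder's first
#' onset. Transitions where the responder starts before the previous
#' speaker has finished are overlaps, counted by [overlap_proportion()],
#' and are excluded here rather than clamped to zero.
#'
#' @param dlg a [dialog()].
#' @param responder optionally restrict to gaps where this channel replies.
#' @return numeric vector of gaps in seconds (all >= 0), possibly empty.
#' @export
turn_taking_gaps <- function(dlg, responder = NULL) {
  ev <- dlg$events
  idx <- utterance_index(ev)
  if (length(idx) == 0 || max(idx) < 2) return(numeric(0))
  last_off <- tapply(ev$offset, idx, function(z) z[length(z)])
  first_on <- tapply(ev$onset, idx, function(z) z[1])
  resp_ch <- tapply(ev$channel, idx, function(z) z[1])
  nu <- max(idx)
  gaps <- first_on[-1] - last_off[-nu]
  who <- resp_ch[-1]
  keep <- gaps >= 0
  if (!is.null(responder)) keep <- keep & who == responder
  as.numeric(gaps[keep])
}

#' Proportion of overlapping whistles for one channel
#'
#' Fraction of the channel's whistles that start before the partner's
#' current whistle has ended, i.e. whose onset falls inside a partner
#' whistle interval `[onset, offset)`.
#'
#' @param dlg a [dialog()].
#' @param channel `"A"` or `"B"`.
#' @return fraction in `[0, 1]`, or `NA` if the channel emitted no whistle.
#' @export
overlap_proportion <- function(dlg, channel) {
  stopifnot(channel %in% .CHANNELS)
  ev <- dlg$events
  mine <- ev[ev$channel == channel, , drop = FALSE]
  other <- ev[ev$channel != channel, , drop = FALSE]
  if (nrow(mine) == 0) return(NA_real_)
  if (nrow(other) == 0) return(0)
  inside <- vapply(mine$onset, function(t)
    any(t >= other$onset & t < other$offset), logical(1))
  mean(inside)
}

#' Score a competitive round
#'
#' A round is resolved when exactly one whistler claims the reward; it is
#' an agreement when, in addition, the loser judged the final reward
#' distribution fair. Rounds where both or neither claimed are unresolved.
#'
#' @param dlg a [dialog()] with claim fields populated.
#' @return list of class `round_outcome` with fields `resolved`, `winner`
#'   (`"A"`/`"B"`/`NA`), `agreement` (logical, `NA` when the relevant
#'   fairness judgment is missing), `unresolved_reason`
#'   (`"both_claimed"`/`"none_claimed"`/`NA`).
#' @export
score_round <- function(dlg) {
  ca <- isTRUE(dlg$claim_A); cb <- isTRUE(dlg$claim_B)
  if (is.na(dlg$claim_A) || is.na(dlg$claim_B))
    stop("claim fields must be populated to score a round")
  out <- list(resolved = xor(ca, cb), winner = NA_character_,
              agreement = NA, unresolved_reason = NA_character_)
  if (out$resolved) {
    out$winner <- if (ca) "A" else "B"
    loser_fair <- if (ca) dlg$fair_B else dlg$fair_A
    out$agreement <- if (is.na(loser_fair)) NA else isTRUE(loser_fair)
  } else {
    out$agreement <- FALSE
    out$unresolved_reason <- if (ca) "both_claimed" else "none_claimed"
  }
  class(out) <- "round_outcome"
  out
}

#' Aggregate round outcomes into the headline contest percentages
#'
#' @param outcomes list of `round_outcome` objects (one per round).
#' @return named list with percentages on a 0-100 scale: `pct_resolved`
#'   (one claimant), `pct_fair_given_resolved` (loser judged it fair, among
#'   resolved rounds with a judgment), `pct_agreement` (of all rounds),
#'   `pct_both_claimed`, `pct_none_claimed`, `pct_unresolved`, and `n`.
#' @export
outcome_summary <- function(outcomes) {
  n <- length(outcomes)
  stopifnot(n > 0)
  res <- vapply(outcomes, `[[`, logical(1), "resolved")
  agr <- vapply(outcomes, function(o) isTRUE(o$agreement), logical(1))
  reason <- vapply(outcomes, function(o)
    if (is.na(o$unresolved_reason)) "" else o$unresolved_reason, character(1))
  judged <- res & !vapply(outcomes, function(o) is.na(o$agreement), logical(1))
  list(n = n,
       pct_resolved = 100 * mean(res),
       pct_fair_given_resolved =
         if (any(judged)) 100 * sum(agr) / sum(judged) else NA_real_,
       pct_agreement = 100 * mean(agr),
       pct_both_claimed = 100 * mean(reason == "both_claimed"),
       pct_none_claimed = 100 * mean(reason == "none_claimed"),
       pct_unresolved = 100 * mean(!res))
}
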