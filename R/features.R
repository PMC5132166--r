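# Per-whistler, per-round acoustic features. Seven variables are computed
# for each channel of a dialog: mean loudness, mean duration, whistle
# count, mean turn-taking gap, overlap proportion, and the two positional
# accentuation measures (duration and loudness of the utterance-initial
# whistle relative to the following whistles). Missingness is propagated,
# never zero-filled: a silent channel yields NA features with n = 0.

.FEATURES <- c("mean_loudness", "mean_duration", "n_whistles",
               "mean_turn_gap", "overlap_prop", "dur_accent", "loud_accent")

#' First-whistle accentuation of a set of utterances
#'
#' For every utterance with at least two whistles, the difference between
#' the first whistle's value and the mean of the following whistles'
#' values; the accentuation is the mean of those per-utterance
#' differences. Single-whistle utterances carry no positional information
#' and are skipped. A positive value means the whistler stresses the
#' utterance-initial whistle — the prosodic signature of contest winners.
#'
#' @param utterances list of `utterance` objects (all one channel), as
#'   returned by [segment_utterances()] after filtering.
#' @param measure `"duration"` or `"loudness"` (loudness uses the event
#'   `mean_amp`).
#' @return mean accentuation, or `NA` if no utterance has >= 2 whistles.
#' @export
accentuation <- function(utterances, measure = c("duration", "loudness")) {
  measure <- match.arg(measure)
  diffs <- vapply(utterances, function(u) {
    ev <- u$events
    if (nrow(ev) < 2) return(NA_real_)
    v <- if (measure == "duration") ev$offset - ev$onset else ev$mean_amp
    v[1] - mean(v[-1])
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0) NA_real_ else mean(diffs)
}

#' Per-channel feature vectors of a dialog
#'
#' @param dlg a [dialog()].
#' @param loudness_measure event field used as "loudness".
#' @return data.frame with one row per channel ("A", "B") and the seven
#'   feature columns; `NA` where a feature is undefined (no whistles, no
#'   valid turn transition, or no multi-whistle utterance).
#' @export
compute_features <- function(dlg, loudness_measure = c("mean_amp", "peak_amp")) {
  loudness_measure <- match.arg(loudness_measure)
  utts <- segment_utterances(dlg)
  ev <- dlg$events
  rows <- lapply(c("A", "B"), function(ch) {
    mine <- ev[ev$channel == ch, , drop = FALSE]
    n <- nrow(mine)
    gaps <- turn_taking_gaps(dlg, responder = ch)
    uch <- Filter(function(u) u$channel == ch, utts)
    data.frame(
      channel = ch,
      mean_loudness = if (n) mean(mine[[loudness_measure]]) else NA_real_,
      mean_duration = if (n) mean(mine$offset - mine$onset) else NA_real_,
      n_whistles = n,
      mean_turn_gap = if (length(gaps)) mean(gaps) else NA_real_,
      overlap_prop = overlap_proportion(dlg, ch),
      dur_accent = accentuation(uch, "duration"),
      loud_accent = if (n) {
        a <- vapply(uch, function(u) {
          e <- u$events
          if (nrow(e) < 2) return(NA_real_)
          v <- e[[loudness_measure]]
          v[1] - mean(v[-1])
        }, numeric(1))
        a <- a[!is.na(a)]
        if (length(a)) mean(a) else NA_real_
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature table for a set of dialogs
#'
#' Convenience wrapper: one row per whistler-round, carrying the dialog
#' metadata (pair, round, condition, winner/agreement when scorable)
#' alongside the seven features.
#'
#' @param dialogs list of [dialog()] objects.
#' @param loudness_measure see [compute_features()].
#' @return data.frame with columns `pair_id`, `round_index`, `condition`,
#'   `channel`, `winner`, `agreement`, and the seven features.
#' @export
feature_table <- function(dialogs, loudness_measure = "mean_amp") {
  rows <- lapply(dialogs, function(d) {
    f <- compute_features(d, loudness_measure)
    win <- NA_character_; agr <- NA
    if (d$condition == "competitive" &&
        !is.na(d$claim_A) && !is.na(d$claim_B)) {
      oc <- score_round(d)
      win <- oc$winner
      agr <- oc$agreement
    }
    cbind(data.frame(pair_id = d$pair_id, round_index = d$round_index,
                     condition = d$condition, winner = win,
                     agreement = agr, stringsAsFactors = FALSE),
          f)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-pair condition means of the acoustic features
#'
#' Implements the two-stage averaging scheme of the contest analysis:
#' whistler-round feature values are averaged within each pair and
#' condition — for a full session that is six whistler-round means per
#' competitive condition (2 whistlers x 3 rounds) and four per
#' non-competitive condition (2 x 2). Missing values are dropped from each
#' mean and the effective n is reported, so silent rounds never fabricate
#' zeros.
#'
#' @param features a [feature_table()]-shaped data.frame.
#' @return data.frame with one row per `pair_id` x `condition` and, per
#'   feature, a `<feature>` mean column and an `n_<feature>` count of
#'   non-missing whistler-round values entering it.
#' @export
condition_means <- function(features) {
  stopifnot(all(c("pair_id", "condition") %in% names(features)))
  key <- interaction(features$pair_id, features$condition, drop = TRUE)
  rows <- lapply(split(features, key), function(g) {
    out <- data.frame(pair_id = g$pair_id[1], condition = g$condition[1],
                      stringsAsFactors = FALSE)
    for (f in .FEATURES) {
      v <- g[[f]]
      out[[f]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      out[[paste0("n_", f)]] <- sum(!is.na(v))
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$pair_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank correlation between accentuation and within-round variability
#'
#' Accentuation is a positional measure; this checks how strongly it
#' tracks plain variability, via the Spearman correlation between the
#' accentuation value and the coefficient of variation (sample sd / mean)
#' of the per-whistle values, one observation per whistler-round.
#'
#' @param accent numeric vector, one accentuation value per whistler-round.
#' @param cv matching coefficient-of-variation vector.
#' @return list of class `wdg_test` with `statistic` (rho), `p_value`,
#'   `n`; constant input is flagged via `notes` and yields `NA` rho.
#' @export
accent_vs_cv <- function(accent, cv) {
  ok <- complete.cases(accent, cv)
  accent <- accent[ok]; cv <- cv[ok]
  n <- length(accent)
  if (n < 3) stop("need >= 3 complete observations")
  if (sd(accent) == 0 || sd(cv) == 0)
    return(structure(list(method = "spearman", statistic = NA_real_,
                          statistic_name = "rho", p_value = NA_real_,
                          n = n, side = "two_sided",
                          notes = "constant input: correlation undefined"),
                     class = "wdg_test"))
  ct <- suppressWarnings(stats::cor.test(accent, cv, method = "spearman"))
  structure(list(method = "spearman", statistic = unname(ct$estimate),
                 statistic_name = "rho", p_value = ct$p.value, n = n,
                 side = "two_sided",
                 notes = "exact p only without ties (stats::cor.test)"),
            class = "wdg_test")
}

#' Coefficient of variation of per-whistle values for one channel
#'
#' Sample (n-1) standard deviation divided by the mean, computed on the
#' channel's per-whistle durations or loudness within one dialog.
#'
#' @param dlg a [dialog()].
#' @param channel `"A"` or `"B"`.
#' @param measure `"duration"` or `"loudness"`.
#' @return the CV, or `NA` with fewer than two whistles.
#' @export
whistle_cv <- function(dlg, channel, measure = c("duration", "loudness")) {
  measure <- match.arg(measure)
  ev <- dlg$events[dlg$events$channel == channel, , drop = FALSE]
  if (nrow(ev) < 2) return(NA_real_)
  v <- if (measure == "duration") ev$offset - ev$onset else ev$mean_amp
  if (mean(v) == 0) return(NA_real_)
  sd(v) / mean(v)
}
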