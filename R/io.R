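# Plain-text interchange: the event-table CSV (one row per whistle, with
# the round metadata repeated), features CSV, listener-response CSV and
# results JSON.

.EVENT_COLS <- c("pair_id", "round_index", "condition", "channel",
                 "onset_s", "offset_s", "peak_amp", "mean_amp",
                 "claim", "fair")

#' Write dialogs to an event-table CSV
#'
#' One row per whistle; `claim`/`fair` repeat each channel's round
#' metadata on its rows. An optional `round_duration_s` column is added so
#' the round length survives the round trip.
#'
#' @param dialogs list of [dialog()] objects.
#' @param path output CSV path.
#' @export
write_event_csv <- function(dialogs, path) {
  rows <- lapply(dialogs, function(d) {
    ev <- d$events
    if (nrow(ev) == 0) return(NULL)
    claim <- ifelse(ev$channel == "A", d$claim_A, d$claim_B)
    fair <- ifelse(ev$channel == "A", d$fair_A, d$fair_B)
    data.frame(pair_id = d$pair_id, round_index = d$round_index,
               condition = d$condition, channel = ev$channel,
               onset_s = ev$onset, offset_s = ev$offset,
               peak_amp = ev$peak_amp, mean_amp = ev$mean_amp,
               claim = claim, fair = fair,
               round_duration_s = d$round_duration,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read dialogs from an event-table CSV
#'
#' Inverse of [write_event_csv()]. The mandatory columns are `pair_id,
#' round_index, condition, channel, onset_s, offset_s, peak_amp,
#' mean_amp, claim, fair`; if `round_duration_s` is absent the round
#' length is taken as the last offset rounded up to the next second.
#' Malformed rows raise an error naming the file and row.
#'
#' @param path CSV path.
#' @return list of [dialog()] objects, ordered by pair then round.
#' @export
read_event_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.EVENT_COLS, names(tab))
  if (length(missing_cols))
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(tab$onset_s) | !is.finite(tab$offset_s) |
                 tab$offset_s <= tab$onset_s | tab$peak_amp < 0 |
                 tab$mean_amp < 0 | !tab$channel %in% c("A", "B"))
  if (length(bad))
    stop(path, ": malformed event at data row ", bad[1])
  key <- interaction(tab$pair_id, tab$round_index, drop = TRUE)
  dialogs <- lapply(split(tab, key), function(g) {
    chan_meta <- function(col, ch) {
      v <- unique(g[[col]][g$channel == ch])
      if (length(v) == 0) NA else as.logical(v[1])
    }
    dur <- if ("round_duration_s" %in% names(g)) max(g$round_duration_s)
           else ceiling(max(g$offset_s))
    dialog(whistle_events(g$channel, g$onset_s, g$offset_s,
                          g$peak_amp, g$mean_amp),
           pair_id = as.character(g$pair_id[1]),
           round_index = g$round_index[1],
           condition = g$condition[1], round_duration = dur,
           claim_A = chan_meta("claim", "A"),
           claim_B = chan_meta("claim", "B"),
           fair_A = chan_meta("fair", "A"),
           fair_B = chan_meta("fair", "B"))
  })
  ord <- order(vapply(dialogs, `[[`, character(1), "pair_id"),
               vapply(dialogs, `[[`, integer(1), "round_index"))
  unname(dialogs[ord])
}

#' Write listener responses to CSV
#' @param responses data.frame from [simulate_listeners()].
#' @param path output path.
#' @export
write_listener_csv <- function(responses, path) {
  write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' Read listener responses from CSV
#' @param path CSV with columns `listener_id, dialog_id, choice,
#'   confidence, truth` (and optionally `correct`, otherwise derived).
#' @export
read_listener_csv <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("listener_id", "dialog_id", "choice", "truth")
  missing_cols <- setdiff(need, names(r))
  if (length(missing_cols))
    stop(path, ": missing columns ", paste(missing_cols, collapse = ", "))
  if (!"correct" %in% names(r)) r$correct <- r$choice == r$truth
  r
}

# Tiny polynomial rolling hash of a deparsed R object (31-bit), for
# stamping reports with the configuration they came from.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Convert nested results (wdg_test / model fits) to JSON-friendly lists.
as_reportable <- function(x) {
  if (inherits(x, "wdg_test")) return(unclass(x))
  if (inherits(x, "paired_model_fit"))
    return(list(term_tests = x$term_tests,
                coefficients = x$coefficients,
                random_effect_variance = x$random_effect_variance,
                interactions_kept = x$interactions_kept,
                n_obs = x$n_obs, n_groups = x$n_groups,
                n_dropped = x$n_dropped, converged = x$converged,
                separation = x$separation, fallback = x$fallback,
                collinearity = x$collinearity))
  if (inherits(x, "listener_concordance"))
    return(list(intercept_test = unclass(x$intercept_test),
                pooled = x$pooled, z_check = unclass(x$z_check),
                per_dialog = x$per_dialog,
                n_listeners = x$n_listeners, n_dialogs = x$n_dialogs,
                separation = x$separation))
  if (is.list(x) && is.null(attr(x, "class"))) return(lapply(x, as_reportable))
  x
}

#' Write an analysis report to JSON
#' @param report named list of results.
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as_reportable(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       dataframe = "rows")
  invisible(path)
}
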