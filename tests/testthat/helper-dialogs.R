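# Shared fixtures: hand-built dialogs and independent oracles.

# Build a dialog from a compact spec: ev = data.frame(channel, onset,
# offset) with optional amplitudes (default 0.1).
mk_dialog <- function(channel, onset, offset, peak = NULL, mean_amp = NULL,
                      ...) {
  n <- length(onset)
  if (is.null(peak)) peak <- rep(0.1, n)
  if (is.null(mean_amp)) mean_amp <- peak
  dialog(whistle_events(channel, onset, offset, peak, mean_amp),
         round_duration = max(offset) + 1, ...)
}

# Random dialog generator for property tests: events on both channels at
# arbitrary (possibly overlapping) times.
random_dialog <- function(n_events, seed) {
  set.seed(seed)
  onset <- sort(runif(n_events, 0, 10))
  dur <- runif(n_events, 0.05, 0.8)
  mk_dialog(sample(c("A", "B"), n_events, replace = TRUE),
            onset, onset + dur, peak = runif(n_events, 0.01, 1))
}

# Independent O(n^2) segmentation oracle: per channel, split between
# consecutive same-channel events whenever any partner onset lies in the
# open interval between their onsets; a partner onset after a channel's
# last event also ends that utterance (vacuously true). Utterances are
# then ordered globally by first onset.
brute_force_segment <- function(dlg) {
  ev <- dlg$events
  if (nrow(ev) == 0) return(list())
  out <- list()
  for (ch in c("A", "B")) {
    mine <- which(ev$channel == ch)
    if (length(mine) == 0) next
    partner_on <- ev$onset[ev$channel != ch]
    cur <- mine[1]
    for (i in seq_along(mine)[-1]) {
      a <- ev$onset[mine[i - 1]]; b <- ev$onset[mine[i]]
      if (any(partner_on > a & partner_on < b)) {
        out[[length(out) + 1]] <- cur
        cur <- mine[i]
      } else cur <- c(cur, mine[i])
    }
    out[[length(out) + 1]] <- cur
  }
  out <- out[order(vapply(out, function(i) ev$onset[i[1]], numeric(1)))]
  lapply(out, function(i) list(channel = ev$channel[i[1]],
                               events = ev[i, , drop = FALSE]))
}

# Utterance signature for comparing segmentations.
utt_signature <- function(utts) {
  vapply(utts, function(u)
    paste(u$channel, paste(round(u$events$onset, 9), collapse = ","),
          sep = ":"), character(1))
}

# Brute-force signed-rank p by enumerating all 2^m sign assignments of the
# absolute differences (the exact null under exchangeability).
brute_force_signrank_p <- function(d, side = "two_sided") {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w <- as.vector(signs %*% r)
  eps <- 1e-9
  switch(side,
         two_sided = mean(abs(w - mu) >= abs(wobs - mu) - eps),
         greater = mean(w - mu >= wobs - mu - eps),
         less = mean(w - mu <= wobs - mu + eps))
}
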