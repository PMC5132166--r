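# Whistle event extraction from waveforms (the pulse-train analysis
# analog) plus loudness equalization and minimal PCM WAV input/output.
# Frequency content is ignored throughout: the analysis uses only
# duration, loudness and timing, so a rectified-and-smoothed amplitude
# envelope carries everything the detector needs.

#' Detector parameters
#'
#' Settings of the amplitude-envelope whistle detector. The threshold and
#' hysteresis are fractions of the channel's peak envelope, which makes
#' detection invariant to the overall recording gain. Events closer than
#' `min_gap` are merged, and events shorter than `min_event_duration` are
#' dropped. The defaults (5 ms envelope window, 0.10 threshold, 0.05
#' hysteresis, 20 ms minimum duration, 30 ms merge gap) are this package's
#' choices for clean close-microphone recordings; the reference
#' pulse-train settings used on the original recordings were never
#' published.
#'
#' @param sample_rate sampling rate in Hz.
#' @param envelope_window moving-average smoothing window, seconds.
#' @param threshold event-start level as a fraction of channel peak.
#' @param hysteresis event-end level, fraction of peak; must be below
#'   `threshold` so the detector does not chatter on noise.
#' @param min_event_duration shortest retained event, seconds.
#' @param min_gap events separated by less than this are merged, seconds.
#' @return list of class `detector_params`.
#' @export
detector_params <- function(sample_rate = 8000, envelope_window = 0.005,
                            threshold = 0.10, hysteresis = 0.05,
                            min_event_duration = 0.020, min_gap = 0.030) {
  p <- list(sample_rate = sample_rate, envelope_window = envelope_window,
            threshold = threshold, hysteresis = hysteresis,
            min_event_duration = min_event_duration, min_gap = min_gap)
  if (!(p$sample_rate > 0) || !(p$envelope_window > 0))
    stop("sample_rate and envelope_window must be positive")
  if (!(p$hysteresis > 0 && p$hysteresis < p$threshold && p$threshold <= 1))
    stop("need 0 < hysteresis < threshold <= 1")
  if (!(p$min_event_duration > 0) || p$min_gap < 0)
    stop("min_event_duration must be > 0 and min_gap >= 0")
  class(p) <- "detector_params"
  p
}

# Rectified signal smoothed by a centered moving average.
amplitude_envelope <- function(x, sample_rate, window) {
  w <- max(1L, round(window * sample_rate))
  if (w %% 2 == 0) w <- w + 1L
  env <- stats::filter(abs(x), rep(1 / w, w), sides = 2)
  env <- as.numeric(env)
  env[is.na(env)] <- 0
  env
}

#' Detect whistle events in a mono waveform
#'
#' Threshold-with-hysteresis detection on the smoothed amplitude envelope:
#' an event opens when the envelope rises to `threshold * peak` and closes
#' when it falls below `hysteresis * peak`. Events closer than `min_gap`
#' are merged (the intervening dip is treated as intra-whistle amplitude
#' modulation), then events shorter than `min_event_duration` are dropped.
#'
#' @param waveform numeric vector, one channel of audio.
#' @param params a [detector_params()].
#' @param channel label ("A" or "B") stamped on the returned events.
#' @return a [whistle_events()] table; empty for silent input.
#' @export
detect_whistles <- function(waveform, params = detector_params(),
                            channel = "A") {
  stopifnot(inherits(params, "detector_params"), channel %in% c("A", "B"))
  if (!all(is.finite(waveform))) stop("waveform must be finite")
  sr <- params$sample_rate
  env <- amplitude_envelope(waveform, sr, params$envelope_window)
  peak <- max(env)
  if (peak <= 0) return(whistle_events())
  hi <- params$threshold * peak
  lo <- params$hysteresis * peak
  # Hysteresis states: runs above `hi` open events; each extends backwards /
  # forwards to where the envelope last crossed `lo`.
  above_lo <- env >= lo
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- which(r$values)
  on <- off <- numeric(0)
  for (s in seg) {
    i0 <- starts[s]; i1 <- ends[s]
    if (max(env[i0:i1]) >= hi) { on <- c(on, i0); off <- c(off, i1) }
  }
  if (length(on) == 0) return(whistle_events())
  # merge events separated by less than min_gap
  if (length(on) > 1) {
    gap <- (on[-1] - off[-length(off)] - 1) / sr
    keep <- c(TRUE, gap >= params$min_gap)
    grp <- cumsum(keep)
    on <- tapply(on, grp, min)
    off <- tapply(off, grp, max)
  }
  dur <- (off - on + 1) / sr
  ok <- dur >= params$min_event_duration
  on <- on[ok]; off <- off[ok]
  if (length(on) == 0) return(whistle_events())
  peak_amp <- mapply(function(a, b) max(env[a:b]), on, off)
  mean_amp <- mapply(function(a, b) mean(env[a:b]), on, off)
  whistle_events(channel = rep(channel, length(on)),
                 onset = (on - 1) / sr, offset = off / sr,
                 peak_amp = peak_amp, mean_amp = mean_amp)
}

#' Equalize mean whistle loudness between the two channels
#'
#' Rescales each channel's event amplitudes by a single per-channel factor
#' (grand mean over both channels divided by the channel mean) so both
#' channels end up with the same mean whistle loudness. This is the
#' playback-preparation step that removes the winner/loser loudness
#' asymmetry while leaving durations, timing and within-channel loudness
#' *pattern* (hence duration accentuation exactly, and loudness
#' accentuation up to the channel factor) untouched.
#'
#' @param dlg a [dialog()] with at least one event on each channel.
#' @param measure which amplitude defines "loudness" (default mean).
#' @return the dialog with rescaled `peak_amp` and `mean_amp`.
#' @export
equalize_loudness <- function(dlg, measure = c("mean_amp", "peak_amp")) {
  measure <- match.arg(measure)
  ev <- dlg$events
  for (ch in c("A", "B"))
    if (sum(ev$channel == ch) == 0)
      stop("equalize_loudness needs at least one event per channel")
  m <- tapply(ev[[measure]], ev$channel, mean)
  grand <- mean(m)  # grand mean of the two channel means
  fac <- grand / m
  f <- as.numeric(fac[ev$channel])
  ev$peak_amp <- ev$peak_amp * f
  ev$mean_amp <- ev$mean_amp * f
  dlg$events <- ev
  dlg
}

#' Render a dialog to a two-channel waveform
#'
#' Synthesizes each whistle as a fixed-frequency sine burst with a short
#' trapezoidal (linear attack/release) envelope scaled to the event's mean
#' amplitude, one channel per whistler. Intended for end-to-end testing of
#' the detector: rendering then [detect_whistles()] should recover the
#' event table.
#'
#' @param dlg a [dialog()].
#' @param sample_rate Hz.
#' @param freq sine frequency, Hz. The default is deliberately
#'   incommensurate with common sample rates so the rectified-and-smoothed
#'   envelope of a burst of amplitude `a` converges to the textbook
#'   rectified-sine mean `2 a / pi`; detected amplitudes therefore recover
#'   the event amplitudes up to that known constant.
#' @param ramp attack/release ramp length, seconds.
#' @return list with numeric vectors `A` and `B` and the `sample_rate`.
#' @export
render_dialog_audio <- function(dlg, sample_rate = 8000, freq = 1259.1,
                                ramp = 0.002) {
  n <- ceiling(dlg$round_duration * sample_rate) + 1L
  out <- list(A = numeric(n), B = numeric(n), sample_rate = sample_rate)
  ev <- dlg$events
  if (nrow(ev) == 0) return(out)
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] * sample_rate) + 1L
    i1 <- min(n, ceiling(ev$offset[i] * sample_rate))
    len <- i1 - i0 + 1L
    if (len <= 0) next
    t <- (seq_len(len) - 1) / sample_rate
    envl <- pmin(1, pmin(t, rev(t)) / ramp)
    burst <- ev$mean_amp[i] * envl * sin(2 * pi * freq * t)
    out[[ev$channel[i]]][i0:i1] <- out[[ev$channel[i]]][i0:i1] + burst
  }
  out
}

# ---- minimal 16-bit PCM WAV I/O -------------------------------------------
# No WAV reader ships with the supported dependency set, so the canonical
# RIFF/WAVE chunk layout is read and written directly (16-bit PCM only).

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param channels list of equal-length numeric vectors (1 = mono,
#'   2 = stereo L/R), samples in `[-1, 1]` after normalization.
#' @param sample_rate Hz.
#' @param path output file.
#' @param normalize rescale so the absolute peak maps to 0.9 full scale.
#' @return `path`, invisibly.
#' @export
write_wav <- function(channels, sample_rate, path, normalize = TRUE) {
  if (is.numeric(channels)) channels <- list(channels)
  nch <- length(channels)
  n <- unique(lengths(channels))
  stopifnot(length(n) == 1, nch %in% c(1L, 2L))
  x <- do.call(rbind, channels)          # interleave channels
  if (normalize) {
    pk <- max(abs(x))
    if (pk > 0) x <- x / pk * 0.9
  }
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * 2L), con, size = 4,
           endian = "little")
  writeBin(nch * 2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return list with `channels` (list of numeric vectors scaled to
#'   `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, integer(), size = 2, endian = "little"),
        nch = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate = readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (fmt$audio_format != 1L || bits != 16L)
        stop("only 16-bit PCM WAV is supported")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16L))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2L, size = 2,
                     endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(fmt)) stop("fmt chunk missing in ", path)
  x <- pcm / 32767
  chans <- lapply(seq_len(fmt$nch), function(c)
    x[seq(c, length(x), by = fmt$nch)])
  list(channels = chans, sample_rate = fmt$sample_rate)
}
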