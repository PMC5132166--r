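# Synthetic two-channel whistle dialogs with ground-truth winner labels.
# The generator emulates the structure the analysis assumes: strictly
# alternating utterances of 3-8 whistles, log-normal whistle durations and
# loudness, gamma turn-taking gaps, occasional overlapped turn starts, and
# a role-dependent accentuation of the utterance-initial whistle. Defaults
# are calibrated to the competitive-round values of the original contest
# study: winner duration accentuation 0.14 s vs. loser 0.07 s, ~41 vs.
# ~36 whistles per minute, mean turn gap 1.4 s, ~4% overlap, and follower
# duration/loudness chosen so the overall competitive whistle means land
# near the reported 0.36 s and 0.13 units (utterance-initial whistles are
# ~1/5.5 of whistles, so follower duration = 0.36 - 0.105/5.5 ~ 0.34 s).

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Generator parameters for synthetic dialogs
#'
#' All whistle-level scales are per role ("winner" / "loser"); for
#' non-competitive rounds use [noncompetitive_params()], where the two
#' roles coincide. Durations and loudness are log-normal, parameterized by
#' their arithmetic mean and the log-scale sd; turn gaps are gamma.
#'
#' @param round_duration round length, seconds.
#' @param utterance_length_range inclusive whistle-count range per
#'   utterance.
#' @param duration_mean mean follower whistle duration, seconds.
#' @param duration_sdlog log-sd of whistle duration.
#' @param loudness_mean mean follower loudness, arbitrary units.
#' @param loudness_sdlog log-sd of loudness.
#' @param accent_delta_winner,accent_delta_loser mean seconds added to
#'   each utterance-initial whistle by role.
#' @param accent_delta_sd between-round sd of the accentuation delta: the
#'   realized delta of a whistler in a round is drawn once per round from
#'   `Normal(role mean, accent_delta_sd)`. Without this variability the
#'   role difference would separate the outcome model perfectly, which no
#'   real dataset shows. The default 0.06 s is calibrated once so that,
#'   at the original study's scale (45 pairs, 3 rounds), the
#'   accent-difference term of the winner model lands at the reported
#'   F of about 10.
#' @param loud_accent_delta_winner,loud_accent_delta_loser mean loudness
#'   units added to each utterance-initial whistle by role.
#' @param loud_accent_delta_sd between-round sd of the loudness delta.
#' @param gap_mean,gap_shape gamma turn-taking-gap mean (s) and shape.
#' @param intra_gap_min,intra_gap_mean within-utterance pause floor and
#'   mean (s); the floor keeps synthetic whistles separable by the
#'   detector's default merge gap.
#' @param overlap_prob target proportion of a channel's whistles that
#'   start before the partner's current whistle has ended (the scale the
#'   overlap feature measures). Only utterance-initial whistles can
#'   overlap, so internally this is converted to a per-turn shift
#'   probability `overlap_prob * mean utterance length`.
#' @param rate_winner,rate_loser target whistles per minute by role; only
#'   their ratio matters (it tilts the utterance-length distribution).
#' @param min_duration floor on whistle duration, seconds.
#' @param loudness_range multiplicative clamp on whistle loudness around
#'   `loudness_mean` (applied after the accent delta). Toy whistles have a
#'   bounded dynamic range; the default `c(0.5, 2.5)` also keeps every
#'   whistle above the default detector's relative threshold so audio
#'   round trips are lossless.
#' @return list of class `generator_params`.
#' @export
generator_params <- function(round_duration = 60,
                             utterance_length_range = c(3L, 8L),
                             duration_mean = 0.34, duration_sdlog = 0.3,
                             loudness_mean = 0.12, loudness_sdlog = 0.3,
                             accent_delta_winner = 0.14,
                             accent_delta_loser = 0.07,
                             accent_delta_sd = 0.06,
                             loud_accent_delta_winner = 0.03,
                             loud_accent_delta_loser = 0.04,
                             loud_accent_delta_sd = 0.05,
                             gap_mean = 1.4, gap_shape = 2,
                             intra_gap_min = 0.08, intra_gap_mean = 0.15,
                             overlap_prob = 0.04,
                             rate_winner = 41, rate_loser = 36,
                             min_duration = 0.06,
                             loudness_range = c(0.5, 2.5)) {
  p <- as.list(environment())
  r <- p$utterance_length_range
  if (length(r) != 2 || r[1] < 1 || r[2] > 20 || r[1] > r[2])
    stop("utterance_length_range must lie within [1, 20]")
  if (p$overlap_prob < 0 || p$overlap_prob > 1)
    stop("overlap_prob must be in [0, 1]")
  for (f in c("round_duration", "duration_mean", "loudness_mean",
              "gap_mean", "gap_shape", "rate_winner", "rate_loser"))
    if (!(p[[f]] > 0)) stop(f, " must be > 0")
  class(p) <- "generator_params"
  p
}

#' Parameters for non-competitive interactions
#'
#' Same machinery with symmetric roles, calibrated to the non-competitive
#' condition (overall whistle duration ~0.25 s and loudness ~0.10 units,
#' accentuation 0.10 s / 0.05 units for both whistlers, gap 1.8 s, ~36
#' whistles per minute, ~3% overlap).
#'
#' @param round_duration seconds (the original sessions used 180 s before
#'   and 120 s after the competitive block).
#' @param ... overrides passed to [generator_params()].
#' @export
noncompetitive_params <- function(round_duration = 180, ...) {
  generator_params(round_duration = round_duration,
                   duration_mean = 0.23, loudness_mean = 0.09,
                   accent_delta_winner = 0.10, accent_delta_loser = 0.10,
                   loud_accent_delta_winner = 0.05,
                   loud_accent_delta_loser = 0.05,
                   gap_mean = 1.8, overlap_prob = 0.031,
                   rate_winner = 36, rate_loser = 36, ...)
}

# Exponentially tilted discrete-uniform utterance-length sampler: weights
# w_i ~ exp(theta * i) over lmin:lmax with theta solved so the mean equals
# the role's target (range midpoint scaled by the whistle-rate ratio).
length_weights <- function(range, target_mean) {
  vals <- seq(range[1], range[2])
  if (length(vals) == 1) return(setNames(1, vals))
  target_mean <- min(max(target_mean, range[1] + 0.05), range[2] - 0.05)
  f <- function(theta) {
    w <- exp(theta * (vals - mean(vals)))
    sum(vals * w) / sum(w) - target_mean
  }
  theta <- stats::uniroot(f, c(-10, 10))$root
  w <- exp(theta * (vals - mean(vals)))
  setNames(w / sum(w), vals)
}

#' Generate one synthetic dialog round
#'
#' Channels alternate utterances until the round is full. The `winner`
#' channel receives the winner-role accentuation deltas and the higher
#' whistle rate; claims are not filled in here (see
#' [generate_session()]). The same seed always reproduces the same
#' dialog.
#'
#' @param params a [generator_params()].
#' @param winner `"A"` or `"B"`: which channel plays the winner role.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param pair_id,round_index,condition dialog metadata.
#' @return a [dialog()] with attribute `winner_role` set to `winner`.
#' @export
generate_dialog <- function(params = generator_params(), winner = "A",
                            seed = NULL, pair_id = "sim", round_index = 0L,
                            condition = "competitive") {
  stopifnot(inherits(params, "generator_params"), winner %in% c("A", "B"))
  with_seed(seed, {
    role <- function(ch) if (ch == winner) "winner" else "loser"
    rate <- c(winner = params$rate_winner, loser = params$rate_loser)
    mid <- mean(params$utterance_length_range)
    wts <- lapply(c(winner = "winner", loser = "loser"), function(r)
      length_weights(params$utterance_length_range,
                     mid * 2 * rate[r] / sum(rate)))
    # realized per-round accentuation deltas: role mean + between-round
    # variability, one draw per channel per round
    accent <- c(winner = rnorm(1, params$accent_delta_winner,
                               params$accent_delta_sd),
                loser = rnorm(1, params$accent_delta_loser,
                              params$accent_delta_sd))
    laccent <- c(winner = rnorm(1, params$loud_accent_delta_winner,
                                params$loud_accent_delta_sd),
                 loser = rnorm(1, params$loud_accent_delta_loser,
                               params$loud_accent_delta_sd))
    dur_meanlog <- log(params$duration_mean) - params$duration_sdlog^2 / 2
    loud_meanlog <- log(params$loudness_mean) - params$loudness_sdlog^2 / 2
    ig_shape <- 2
    ig_scale <- (params$intra_gap_mean - params$intra_gap_min) / ig_shape

    ch <- sample(c("A", "B"), 1)
    t <- runif(1, 0.2, 1.5)          # first onset
    rows <- vector("list", 256); nr <- 0
    prev_last_onset <- prev_last_offset <- NA_real_
    repeat {
      r <- role(ch)
      L <- as.integer(sample(names(wts[[r]]), 1, prob = wts[[r]]))
      placed <- 0
      for (k in seq_len(L)) {
        d <- max(params$min_duration,
                 rlnorm(1, dur_meanlog, params$duration_sdlog) +
                   if (k == 1) accent[[r]] else 0)
        a <- rlnorm(1, loud_meanlog, params$loudness_sdlog) +
          if (k == 1) laccent[[r]] else 0
        a <- min(max(a, params$loudness_range[1] * params$loudness_mean),
                 params$loudness_range[2] * params$loudness_mean)
        if (t + d > params$round_duration) break
        nr <- nr + 1
        if (nr > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nr]] <- list(channel = ch, onset = t, offset = t + d,
                           peak_amp = a, mean_amp = a)
        placed <- placed + 1
        last_onset <- t; last_offset <- t + d
        t <- t + d + params$intra_gap_min + rgamma(1, ig_shape, scale = ig_scale)
      }
      if (placed == 0) break
      # partner's turn: gamma gap, or an overlapped start. The per-turn
      # shift probability is scaled so the per-whistle overlap fraction
      # matches overlap_prob.
      next_role <- role(setdiff(c("A", "B"), ch))
      m_next <- sum(as.integer(names(wts[[next_role]])) * wts[[next_role]])
      if (runif(1) < min(1, params$overlap_prob * m_next)) {
        # overlapped start, with a 20 ms guard band at both ends so the
        # overlap stays unambiguous at the detector's time resolution
        dur_last <- last_offset - last_onset
        t <- last_offset - runif(1, min(0.02, dur_last / 3),
                                 dur_last - min(0.02, dur_last / 3))
      } else {
        # floor keeps responder onsets clear of the partner's offset
        t <- last_offset +
          max(0.05, rgamma(1, params$gap_shape,
                           scale = params$gap_mean / params$gap_shape))
      }
      prev_last_onset <- last_onset; prev_last_offset <- last_offset
      ch <- setdiff(c("A", "B"), ch)
      if (t >= params$round_duration) break
    }
    if (nr == 0)
      stop("round_duration too short to fit a single whistle")
    rows <- rows[seq_len(nr)]
    ev <- whistle_events(
      channel = vapply(rows, `[[`, character(1), "channel"),
      onset = vapply(rows, `[[`, numeric(1), "onset"),
      offset = vapply(rows, `[[`, numeric(1), "offset"),
      peak_amp = vapply(rows, `[[`, numeric(1), "peak_amp"),
      mean_amp = vapply(rows, `[[`, numeric(1), "mean_amp"))
    d <- dialog(ev, pair_id = pair_id, round_index = round_index,
                condition = condition,
                round_duration = params$round_duration)
    attr(d, "winner_role") <- winner
    d
  })
}

#' Generate a full session for one pair
#'
#' One pre-competition non-competitive interaction, three competitive
#' rounds of one minute, and one post-competition non-competitive
#' interaction. The round winner is drawn independently each round; the
#' end-of-round claims and the fairness judgment are then sampled at the
#' stated rates so that, in expectation, 88% of rounds are resolved
#' (claimed by exactly one whistler), 82% of resolved rounds are judged
#' fair, and unresolved rounds split 7:5 between double claims and no
#' claim.
#'
#' @param pair_id pair identifier.
#' @param seed integer seed.
#' @param comp_params,noncomp_params generator parameter sets.
#' @param p_resolved probability a round is claimed by the winner alone.
#' @param p_both_given_unresolved probability an unresolved round is a
#'   double claim (vs. no claim).
#' @param p_fair probability the loser judges a resolved round fair (at a
#'   between-partner accentuation gap equal to `accent_link_center`).
#' @param agreement_accent_link logit-scale slope linking the fairness
#'   probability to the round's measured absolute duration-accentuation
#'   difference between partners; 0 (default) keeps fairness independent
#'   of the acoustics so the marginal rates stay at their stated values.
#' @param accent_link_center accentuation gap (s) at which the link leaves
#'   `p_fair` unchanged.
#' @param post_duration duration of the closing non-competitive round, s.
#' @return list of 5 [dialog()]s (rounds 0..4; rounds 1-3 competitive).
#' @export
generate_session <- function(pair_id, seed = NULL,
                             comp_params = generator_params(),
                             noncomp_params = noncompetitive_params(),
                             p_resolved = 0.88,
                             p_both_given_unresolved = 7 / 12,
                             p_fair = 0.815,
                             agreement_accent_link = 0,
                             accent_link_center = 0.15,
                             post_duration = 120) {
  with_seed(seed, {
    pre <- generate_dialog(noncomp_params, winner = "A", pair_id = pair_id,
                           round_index = 0L, condition = "non_competitive")
    post_p <- noncomp_params; post_p$round_duration <- post_duration
    rounds <- lapply(1:3, function(i) {
      w <- sample(c("A", "B"), 1)
      d <- generate_dialog(comp_params, winner = w, pair_id = pair_id,
                           round_index = i, condition = "competitive")
      if (runif(1) < p_resolved) {
        d$claim_A <- w == "A"; d$claim_B <- w == "B"
      } else if (runif(1) < p_both_given_unresolved) {
        d$claim_A <- TRUE; d$claim_B <- TRUE
      } else {
        d$claim_A <- FALSE; d$claim_B <- FALSE
      }
      p_f <- p_fair
      if (agreement_accent_link != 0) {
        f <- compute_features(d)
        gap <- abs(f$dur_accent[1] - f$dur_accent[2])
        if (is.finite(gap))
          p_f <- plogis(stats::qlogis(p_fair) +
                          agreement_accent_link * (gap - accent_link_center))
      }
      fair <- runif(1) < p_f
      d$fair_A <- if (w == "B") fair else TRUE
      d$fair_B <- if (w == "A") fair else TRUE
      d
    })
    post <- generate_dialog(post_p, winner = "A", pair_id = pair_id,
                            round_index = 4L, condition = "non_competitive")
    c(list(pre), rounds, list(post))
  })
}

#' Rearrange utterances so the longest whistle is first or in the middle
#'
#' The accentuation-playback construction: each utterance's whistles are
#' permuted so its longest whistle sits at the first position (high
#' duration accentuation) or at the middle position, index
#' `floor(n/2)` counting from 0 (low accentuation). The remaining
#' whistles keep their relative order, so the two variants of an
#' utterance contain exactly the same whistles. Ties for longest go to
#' the earliest original position.
#'
#' @param utterances list of numeric whistle-duration vectors, each of
#'   length 3 to 8.
#' @param position `"first"` or `"middle"`.
#' @return list of permuted duration vectors.
#' @export
synthesize_playback <- function(utterances, position = c("first", "middle")) {
  position <- match.arg(position)
  lapply(utterances, function(d) {
    n <- length(d)
    if (n < 3 || n > 8)
      stop("each playback utterance must contain 3 to 8 whistles")
    i_long <- which.max(d)                # earliest position wins ties
    target <- if (position == "first") 1L else floor(n / 2) + 1L
    rest <- d[-i_long]
    append(rest, d[i_long], after = target - 1L)
  })
}

#' Listener response model
#'
#' @param p_choose_accentuated probability a listener designates the
#'   first-whistle-accentuating (ground-truth winner) channel; the default
#'   0.7 is the concordance level observed in the original playback
#'   experiment.
#' @param confidence_probs probabilities of the three confidence levels
#'   (defaults follow the reported 40% "sure" / 16% "not sure" split).
#' @return list of class `listener_model`.
#' @export
listener_model <- function(p_choose_accentuated = 0.7,
                           confidence_probs = c(sure = 0.40,
                                                not_totally_sure = 0.44,
                                                not_sure = 0.16)) {
  stopifnot(p_choose_accentuated >= 0, p_choose_accentuated <= 1,
            length(confidence_probs) == 3,
            abs(sum(confidence_probs) - 1) < 1e-8)
  structure(list(p_choose_accentuated = p_choose_accentuated,
                 confidence_probs = confidence_probs),
            class = "listener_model")
}

#' Simulate listener winner designations
#'
#' Independent Bernoulli choices: each listener hears each dialog and
#' designates the accentuated (ground-truth winner) channel with the
#' model's probability; confidence is drawn independently of correctness.
#'
#' @param model a [listener_model()].
#' @param n_listeners,n_dialogs counts.
#' @param seed integer seed.
#' @return data.frame: `listener_id`, `dialog_id`, `truth` (winner
#'   channel), `choice`, `confidence`, `correct`.
#' @export
simulate_listeners <- function(model = listener_model(), n_listeners = 30,
                               n_dialogs = 4, seed = NULL) {
  stopifnot(inherits(model, "listener_model"))
  with_seed(seed, {
    truth <- sample(c("A", "B"), n_dialogs, replace = TRUE)
    g <- expand.grid(listener_id = seq_len(n_listeners),
                     dialog_id = seq_len(n_dialogs))
    correct <- runif(nrow(g)) < model$p_choose_accentuated
    tr <- truth[g$dialog_id]
    data.frame(
      listener_id = g$listener_id, dialog_id = g$dialog_id, truth = tr,
      choice = ifelse(correct, tr, ifelse(tr == "A", "B", "A")),
      confidence = sample(names(model$confidence_probs), nrow(g),
                          replace = TRUE, prob = model$confidence_probs),
      correct = correct, stringsAsFactors = FALSE)
  })
}

#' Simulate per-round contest records from a logistic mixed model
#'
#' Direct simulator for the outcome-model world, bypassing audio: each
#' pair contributes `n_rounds` rows with standardized acoustic-difference
#' predictors, a pair-level random intercept, and a Bernoulli outcome on
#' the logit scale. Used for parameter-recovery and type-I-error checks
#' of [winner_model()].
#'
#' @param n_pairs,n_rounds design size.
#' @param beta named fixed-effect vector over predictor columns.
#' @param sigma_pair sd of the pair random intercept.
#' @param beta0 intercept on the logit scale.
#' @param seed integer seed.
#' @return data.frame with `pair_id`, `round_index`, `outcome` and one
#'   column per name of `beta` (predictors i.i.d. standard normal).
#' @export
simulate_round_records <- function(n_pairs = 45, n_rounds = 3,
                                   beta = c(d_dur_accent = 2),
                                   sigma_pair = 0.5, beta0 = 0,
                                   seed = NULL) {
  with_seed(seed, {
    n <- n_pairs * n_rounds
    df <- data.frame(pair_id = rep(sprintf("p%02d", seq_len(n_pairs)),
                                   each = n_rounds),
                     round_index = rep(seq_len(n_rounds), n_pairs))
    eta <- beta0 + rep(rnorm(n_pairs, 0, sigma_pair), each = n_rounds)
    for (nm in names(beta)) {
      df[[nm]] <- rnorm(n)
      eta <- eta + beta[[nm]] * df[[nm]]
    }
    df$outcome <- as.integer(runif(n) < plogis(eta))
    df
  })
}
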