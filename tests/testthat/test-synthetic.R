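test_that("generate_dialog is deterministic in its seed", {
  d1 <- generate_dialog(seed = 123, winner = "A")
  d2 <- generate_dialog(seed = 123, winner = "A")
  expect_identical(d1$events, d2$events)
  d3 <- generate_dialog(seed = 124, winner = "A")
  expect_false(identical(d1$events, d3$events))

  # seeding does not disturb the caller's RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(generate_dialog(seed = 9, winner = "B"))
  expect_identical(runif(3), before)
})

test_that("generated dialogs respect their structural contract", {
  for (s in 1:10) {
    d <- generate_dialog(seed = s, winner = sample(c("A", "B"), 1))
    ev <- d$events
    expect_true(all(ev$onset >= 0 & ev$offset <= d$round_duration))
    expect_true(all(ev$offset > ev$onset))
    for (ch in c("A", "B")) {
      e <- ev[ev$channel == ch, ]
      if (nrow(e) > 1)            # non-overlapping within channel
        expect_true(all(e$onset[-1] >= e$offset[-nrow(e)]))
    }
    lens <- vapply(segment_utterances(d), function(u) nrow(u$events),
                   integer(1))
    expect_true(all(lens >= 1 & lens <= 8))
  }
  expect_error(generate_dialog(generator_params(round_duration = 0.05),
                               seed = 1), "short")
  expect_error(generator_params(utterance_length_range = c(0, 8)))
  expect_error(generator_params(overlap_prob = 1.5))
})

test_that("generator round-trip recovers injected parameters", {
  # 200 replicate dialogs; each injected scale must be recovered within
  # 3 Monte-Carlo standard errors
  p <- generator_params()
  n_rep <- 200
  acc_w <- acc_l <- gap <- ovl <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- generate_dialog(p, seed = 20000 + i, winner = "A")
    f <- compute_features(d)
    acc_w[i] <- f$dur_accent[f$channel == "A"]
    acc_l[i] <- f$dur_accent[f$channel == "B"]
    g <- turn_taking_gaps(d)
    gap[i] <- if (length(g)) mean(g) else NA
    ovl[i] <- mean(f$overlap_prop, na.rm = TRUE)
  }
  mc_ok <- function(x, target, extra_tol = 0) {
    x <- x[!is.na(x)]
    se <- sd(x) / sqrt(length(x))
    abs(mean(x) - target) <= 3 * se + extra_tol
  }
  # role accent deltas (floor truncation adds a small positive bias to
  # heavily negative draws; allow 0.01 s on top of the MC band)
  expect_true(mc_ok(acc_w, p$accent_delta_winner, 0.01))
  expect_true(mc_ok(acc_l, p$accent_delta_loser, 0.01))
  expect_true(mc_ok(gap, p$gap_mean, 0.02))
  expect_true(mc_ok(ovl, p$overlap_prob, 0.005))

  # null accentuation: measured accent centred on zero
  p0 <- generator_params(accent_delta_winner = 0, accent_delta_loser = 0,
                         accent_delta_sd = 0)
  acc0 <- vapply(1:200, function(i) {
    f <- compute_features(generate_dialog(p0, seed = 40000 + i,
                                          winner = "A"))
    mean(f$dur_accent, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(acc0)), 2 * sd(acc0) / sqrt(length(acc0)) + 0.005)

  # injected contrast: winner-minus-loser accent difference ~ 0.1 s
  pd <- generator_params(accent_delta_winner = 0.1, accent_delta_loser = 0,
                         accent_delta_sd = 0)
  dd <- vapply(1:100, function(i) {
    f <- compute_features(generate_dialog(pd, seed = 60000 + i,
                                          winner = "A"))
    f$dur_accent[1] - f$dur_accent[2]
  }, numeric(1))
  expect_equal(mean(dd), 0.1,
               tolerance = 3 * sd(dd) / sqrt(length(dd)) / 0.1 + 0.1)
})

test_that("generate_session produces the stated round structure", {
  s <- generate_session("pairX", seed = 42)
  expect_length(s, 5)
  expect_equal(vapply(s, `[[`, character(1), "condition"),
               c("non_competitive", rep("competitive", 3),
                 "non_competitive"))
  expect_equal(vapply(s, `[[`, numeric(1), "round_duration"),
               c(180, 60, 60, 60, 120))
  comp <- s[2:4]
  expect_true(all(!is.na(vapply(comp, `[[`, logical(1), "claim_A"))))
  expect_identical(generate_session("pairX", seed = 42)[[3]]$events,
                   s[[3]]$events)
})

test_that("playback permutation puts the longest whistle where asked", {
  expect_equal(synthesize_playback(list(c(0.2, 0.5, 0.3)), "first")[[1]],
               c(0.5, 0.2, 0.3))
  expect_equal(synthesize_playback(list(c(0.2, 0.5, 0.3)), "middle")[[1]],
               c(0.2, 0.5, 0.3))   # floor(3/2) = 1 (0-based) = position 2

  # even length: middle is index floor(n/2), 0-based
  expect_equal(synthesize_playback(list(c(0.4, 0.1, 0.2, 0.3)),
                                   "middle")[[1]],
               c(0.1, 0.2, 0.4, 0.3))
  # ties: earliest original position wins
  expect_equal(synthesize_playback(list(c(0.2, 0.5, 0.5)), "first")[[1]],
               c(0.5, 0.2, 0.5))

  # permutation invariant: the two variants hold the same whistles
  set.seed(8)
  utts <- replicate(10, runif(sample(3:8, 1), 0.1, 0.6), simplify = FALSE)
  f <- synthesize_playback(utts, "first")
  m <- synthesize_playback(utts, "middle")
  for (i in 1:10) {
    expect_equal(sort(f[[i]]), sort(m[[i]]))
    expect_equal(sort(f[[i]]), sort(utts[[i]]))
    expect_equal(f[[i]][1], max(utts[[i]]))
    expect_equal(m[[i]][floor(length(m[[i]]) / 2) + 1], max(utts[[i]]))
  }
  # first-variant accentuation exceeds middle-variant accentuation
  acc <- function(us) mean(vapply(us, function(v) v[1] - mean(v[-1]),
                                  numeric(1)))
  expect_gt(acc(f), acc(m))

  expect_error(synthesize_playback(list(c(0.2, 0.3)), "first"), "3 to 8")
})

test_that("simulated listeners follow the response model", {
  expect_true(all(simulate_listeners(listener_model(1), 20, 3,
                                     seed = 1)$correct))
  r0 <- simulate_listeners(listener_model(0.5), 100, 100, seed = 2)
  phat <- mean(r0$correct)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / nrow(r0)))

  # the reported 70% regime: mean correct count near 21/30
  ks <- vapply(1:200, function(s)
    sum(simulate_listeners(listener_model(0.7), 30, 1, seed = s)$correct),
    numeric(1))
  expect_equal(mean(ks), 21, tolerance = 3 * sd(ks) / sqrt(200) / 21 + 0.02)

  r <- simulate_listeners(seed = 11)
  expect_identical(r, simulate_listeners(seed = 11))
  expect_setequal(unique(r$choice), c("A", "B"))
  expect_true(all(r$correct == (r$choice == r$truth)))
  expect_error(listener_model(1.2))
  expect_error(listener_model(confidence_probs = c(0.5, 0.5, 0.5)))
})

test_that("simulate_round_records builds the stated logistic world", {
  r <- simulate_round_records(n_pairs = 10, beta = c(x1 = 0, x2 = 1),
                              seed = 3)
  expect_equal(nrow(r), 30)
  expect_setequal(names(r), c("pair_id", "round_index", "outcome",
                              "x1", "x2"))
  expect_identical(r, simulate_round_records(n_pairs = 10,
                                             beta = c(x1 = 0, x2 = 1),
                                             seed = 3))
  # a strong positive effect raises the outcome rate with the predictor
  big <- simulate_round_records(n_pairs = 400, beta = c(x = 3), seed = 4)
  expect_gt(mean(big$outcome[big$x > 1]), 0.85)
  expect_lt(mean(big$outcome[big$x < -1]), 0.15)
})
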