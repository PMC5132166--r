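test_that("signed-rank statistic follows the centered-S convention", {
  r0 <- paired_signed_rank(1:4, 1:4)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # all positive, no ties: W+ = 15, S = 15 - 7.5
  r1 <- paired_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r1$statistic, 7.5)
  expect_equal(r1$p_value, 2 / 32)          # both extreme tails of 2^5
  expect_equal(paired_signed_rank(c(1, 1, 1, 1, 1),
                                  c(2, 3, 4, 5, 6))$statistic, -7.5)

  # zero differences are dropped
  r2 <- paired_signed_rank(c(1, 5, 7), c(1, 2, 3))
  expect_equal(r2$n, 2)
})

test_that("exact signed-rank p matches brute-force sign-flip enumeration", {
  set.seed(314)
  for (rep in 1:25) {
    m <- sample(3:12, 1)
    # mix of clean and heavily tied differences
    d <- if (rep %% 2) round(rnorm(m), 0) else rnorm(m)
    d[d == 0] <- 0.5
    for (side in c("two_sided", "greater", "less")) {
      got <- paired_signed_rank(d, numeric(m), side = side)
      expect_equal(got$p_value, brute_force_signrank_p(d, side),
                   tolerance = 1e-12,
                   info = paste("rep", rep, side))
    }
  }
  # no-tie case also agrees with the classical distribution
  d <- c(1.3, -0.4, 2.2, 0.9, -1.7, 0.2, 3.1, -2.5)
  got <- paired_signed_rank(d, numeric(8), side = "greater")
  w <- sum(rank(abs(d))[d > 0])
  expect_equal(got$p_value, 1 - psignrank(w - 1, 8))
})

test_that("large-sample signed-rank uses the tie-corrected normal tail", {
  set.seed(99)
  x <- rnorm(40, 0.3); y <- rnorm(40)
  got <- paired_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_match(got$notes, "normal")
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("binomial Z test matches the closed form and the exact tail", {
  r <- binomial_z_test(21, 30, 0.5)
  expect_equal(r$statistic, 2.19, tolerance = 0.005)
  expect_equal(r$p_value, 0.014, tolerance = 0.05)
  expect_equal(r$exact_p, pbinom(20, 30, 0.5, lower.tail = FALSE))

  expect_equal(binomial_z_test(15, 30, 0.5)$statistic, 0)
  expect_equal(binomial_z_test(15, 30, 0.5)$p_value, 0.5)
  expect_equal(binomial_z_test(30, 30, 0.5)$statistic,
               0.5 / sqrt(0.25 / 30), tolerance = 1e-12)

  # antisymmetry of Z in k around n * p0
  for (k in 0:15)
    expect_equal(binomial_z_test(15 + k, 30, 0.5)$statistic,
                 -binomial_z_test(15 - k, 30, 0.5)$statistic)

  # without continuity correction the normal tail approximates the mid-P
  # tail (exact tail minus half the point mass); agreement within 0.02
  # throughout the moderate-deviation regime
  for (n in c(30, 50, 100)) for (k in seq(ceiling(n / 2), n)) {
    r <- binomial_z_test(k, n, 0.5)
    if (abs(r$statistic) <= 2.5) {
      midp <- r$exact_p - 0.5 * dbinom(k, n, 0.5)
      expect_lt(abs(r$p_value - midp), 0.02)
    }
  }
  expect_error(binomial_z_test(1, 0, 0.5))
})

test_that("within_subject_change pairs condition means and reports drops", {
  r <- within_subject_change(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- within_subject_change(c(1, 2, NA, 4), c(0, 1, 5, NA))
  expect_equal(r2$n_excluded, 2)
  expect_equal(r2$n, 2)
})

test_that("outcome_glmm contract: constants, relabeling, separation", {
  rec <- simulate_round_records(n_pairs = 30,
                                beta = c(x1 = 1.5, x2 = 0), seed = 10)
  rec$const <- 1
  fit <- outcome_glmm(rec, "outcome", c("x1", "x2", "const"),
                      interactions = FALSE)
  expect_equal(fit$dropped_constant, "const")
  expect_false("const" %in% fit$term_tests$term)
  expect_true(all(fit$term_tests$p >= 0 & fit$term_tests$p <= 1))
  expect_equal(fit$n_obs, 90)
  expect_equal(fit$n_groups, 30)

  # relabeling: negating the predictors flips the coefficients only
  rec2 <- rec; rec2$x1 <- -rec2$x1; rec2$x2 <- -rec2$x2
  fit2 <- outcome_glmm(rec2, "outcome", c("x1", "x2"),
                       interactions = FALSE)
  co1 <- fit$coefficients; co2 <- fit2$coefficients
  for (tm in c("x1", "x2"))
    expect_equal(co2$estimate[co2$term == tm],
                 -co1$estimate[co1$term == tm], tolerance = 1e-4)

  # perfectly separated outcome: flagged, Firth fallback keeps SEs finite
  sep <- data.frame(pair_id = rep(1:10, each = 3),
                    round_index = rep(1:3, 10),
                    x = rnorm(30))
  sep$outcome <- as.integer(sep$x > 0)
  fs <- outcome_glmm(sep, "outcome", "x", interactions = FALSE)
  expect_true(fs$separation)
  expect_equal(fs$fallback, "firth_penalized_fixed_effects")
  expect_true(all(is.finite(fs$coefficients$se)))

  # missing predictor rows are dropped and counted
  rec3 <- rec; rec3$x1[1:5] <- NA
  f3 <- outcome_glmm(rec3, "outcome", c("x1", "x2"), interactions = FALSE)
  expect_equal(f3$n_dropped, 5)
  expect_equal(f3$n_obs, 85)
})

test_that("winner and agreement models run on generated feature tables", {
  dialogs <- unlist(lapply(1:12, function(i)
    generate_session(sprintf("p%02d", i), seed = 700 + i)),
    recursive = FALSE)
  ft <- feature_table(dialogs)
  wm <- winner_model(ft, seed = 5)
  expect_s3_class(wm, "paired_model_fit")
  expect_true(all(grepl("^d_|round_index",
                        wm$term_tests$term)))
  expect_equal(length(wm$focal), 12)
  expect_lte(wm$n_obs, 36)

  am <- agreement_model(ft)
  expect_true(all(grepl("^ad_|round_index", am$term_tests$term)))
  # absolute differences: invariant to channel relabeling by construction
  expect_true(all(is.finite(am$coefficients$estimate)))

  # agreement model recovers a strong accent-gap effect
  dialogs2 <- unlist(lapply(1:30, function(i)
    generate_session(sprintf("q%02d", i), seed = 900 + i,
                     agreement_accent_link = 12, p_fair = 0.5)),
    recursive = FALSE)
  am2 <- agreement_model(feature_table(dialogs2),
                         features_used = "dur_accent")
  est <- am2$coefficients
  expect_gt(est$estimate[est$term == "ad_dur_accent"], 0)
})

test_that("listener concordance model behaves across regimes", {
  r <- simulate_listeners(listener_model(0.7), 30, 3, seed = 21)
  lc <- listener_concordance(r)
  expect_equal(lc$pooled$n, 90)
  expect_equal(lc$pooled$proportion, mean(r$correct))
  expect_false(lc$separation)
  expect_equal(lc$z_check$k, sum(r$correct))
  expect_equal(nrow(lc$per_dialog), 3)

  # all-correct responses: separation flagged, exact check still usable
  rall <- r; rall$correct <- TRUE
  lca <- listener_concordance(rall)
  expect_true(lca$separation)
  expect_equal(lca$pooled$proportion, 1)
  expect_lt(lca$z_check$exact_p, 1e-20)

  # single dialog: reduced to a listener-only random effect, flagged
  r1 <- simulate_listeners(listener_model(0.7), 30, 1, seed = 22)
  lc1 <- listener_concordance(r1)
  expect_true(lc1$single_dialog)
  expect_match(lc1$intercept_test$notes, "single dialog")
  expect_error(listener_concordance(r[r$listener_id == 1, ]), "listeners")
})

test_that("null and non-null intercept behavior of the concordance test", {
  # p = 0.7 regime: intercept significantly positive in most replicates
  hits <- vapply(1:20, function(s) {
    lc <- listener_concordance(
      simulate_listeners(listener_model(0.7), 30, 3, seed = 3000 + s))
    !lc$separation && lc$intercept_test$p_value < 0.05 &&
      lc$intercept_test$estimate > 0
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  # p = 0.5: mostly nonsignificant
  null_hits <- vapply(1:20, function(s) {
    lc <- listener_concordance(
      simulate_listeners(listener_model(0.5), 30, 3, seed = 4000 + s))
    !lc$separation && lc$intercept_test$p_value < 0.05
  }, logical(1))
  expect_lt(mean(null_hits), 0.5)
})
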