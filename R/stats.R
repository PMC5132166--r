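# The contest statistics: paired Wilcoxon signed-rank comparisons with an
# exact small-sample null, the normal-approximation binomial test against
# chance, and binomial (logit) mixed models for round outcome, agreement
# and listener designation, with a Firth-penalized fallback when the
# binary response separates.

new_test_result <- function(method, statistic, statistic_name, p_value, n,
                            side, notes = "", ...) {
  structure(c(list(method = method, statistic = statistic,
                   statistic_name = statistic_name, p_value = p_value,
                   n = n, side = side, notes = notes), list(...)),
            class = "wdg_test")
}

#' @export
print.wdg_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %d, %s)\n", x$method,
              x$statistic_name, x$statistic, x$p_value, x$n, x$side))
  if (nzchar(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

# Exact null distribution of 2*W+ (doubled positive-rank sum, so mid-ranks
# become integers) via generating-function convolution over the ranks.
# Returns a probability vector over support 0:sum(2r).
signed_rank_null <- function(ranks2) {
  probs <- 1
  for (r in ranks2) {
    nxt <- numeric(length(probs) + r)
    nxt[seq_along(probs)] <- probs / 2
    nxt[seq_along(probs) + r] <- nxt[seq_along(probs) + r] + probs / 2
    probs <- nxt
  }
  probs
}

#' Paired Wilcoxon signed-rank test
#'
#' Differences are `x - y`; zero differences are dropped and tied absolute
#' differences share mid-ranks. The reported statistic is the centered
#' `S = W+ - m(m+1)/4` (positive-rank sum minus its null mean over the `m`
#' nonzero differences), so `S > 0` means `x` tends to exceed `y`. The
#' p-value is exact (full sign-flip null distribution, tie-aware) for
#' `m <= 25` and a tie-corrected normal approximation beyond.
#'
#' @param x,y paired numeric vectors.
#' @param side `"two_sided"` (default), `"greater"` (`x > y`) or
#'   `"less"`.
#' @return a `wdg_test` with `statistic` S.
#' @export
paired_signed_rank <- function(x, y, side = c("two_sided", "greater", "less")) {
  side <- match.arg(side)
  stopifnot(length(x) == length(y), length(x) >= 1)
  ok <- complete.cases(x, y)
  d <- (x - y)[ok]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    return(new_test_result("wilcoxon_signed_rank", 0, "S", 1,
                           sum(ok), side, "all differences zero"))
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  s <- wplus - mu
  if (m <= 25) {
    probs <- signed_rank_null(2 * r)
    support <- seq_along(probs) - 1          # values of 2*W+
    dev <- support / 2 - mu
    eps <- 1e-9
    p <- switch(side,
      two_sided = sum(probs[abs(dev) >= abs(s) - eps]),
      greater = sum(probs[dev >= s - eps]),
      less = sum(probs[dev <= s + eps]))
    notes <- "exact sign-flip null"
  } else {
    ties <- table(r)
    v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- s / sqrt(v)
    p <- switch(side,
      two_sided = 2 * pnorm(-abs(z)),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z))
    notes <- "normal approximation with tie correction"
  }
  new_test_result("wilcoxon_signed_rank", s, "S", min(1, p), m, side, notes)
}

#' Binomial test of a proportion against a null value
#'
#' Normal-approximation Z statistic without continuity correction,
#' `Z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`; the exact binomial tail is
#' reported alongside in `exact_p`.
#'
#' @param k successes, `n` trials, `p0` null proportion.
#' @param side `"greater"` (default, the one-sided test of exceeding
#'   chance), `"less"` or `"two_sided"`.
#' @return a `wdg_test` with `statistic` Z and field `exact_p`.
#' @export
binomial_z_test <- function(k, n, p0 = 0.5,
                            side = c("greater", "less", "two_sided")) {
  side <- match.arg(side)
  if (n < 1) stop("n must be >= 1")
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  p <- switch(side,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two_sided = 2 * pnorm(-abs(z)))
  exact <- switch(side,
    greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = stats::pbinom(k, n, p0),
    two_sided = min(1, stats::binom.test(k, n, p0)$p.value))
  new_test_result("binomial_z", z, "Z", p, n, side,
                  "no continuity correction; exact tail in exact_p",
                  exact_p = exact, k = k, p0 = p0)
}

#' Within-unit change between two conditions
#'
#' Pairs each unit's mean under two conditions (agreement vs. disagreement
#' rounds, or winner vs. loser rounds of the same individual) and
#' delegates to [paired_signed_rank()]. Units missing either condition are
#' excluded and counted.
#'
#' @param x,y per-unit condition means (equal length; `NA` allowed).
#' @param side passed through.
#' @return a `wdg_test`; `n_excluded` records incomplete units.
#' @export
within_subject_change <- function(x, y, side = "two_sided") {
  ok <- complete.cases(x, y)
  res <- paired_signed_rank(x[ok], y[ok], side = side)
  res$n_excluded <- sum(!ok)
  if (res$n_excluded > 0)
    res$notes <- paste0(res$notes, "; ", res$n_excluded,
                        " incomplete units excluded")
  res
}

# ---- binomial mixed models ------------------------------------------------

# Firth-penalized logistic regression (fixed effects only): the fallback
# when the mixed model separates. Jeffreys-prior score adjustment via the
# hat diagonal, standard IRLS.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  b <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    infoinv <- solve(info)
    h <- rowSums((XW %*% infoinv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(infoinv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(infoinv))
  list(coef = setNames(b, colnames(X)), se = setNames(se, colnames(X)),
       iter = it, converged = it < max_iter)
}

# Wald term tests with a between-within style denominator df:
# ddf = n_obs - n_groups - (n_fixed - 1), floored at 1.
wald_term_tests <- function(coefs, ses, n_obs, n_groups) {
  terms <- setdiff(names(coefs), "(Intercept)")
  ddf <- max(1, n_obs - n_groups - (length(coefs) - 1))
  do.call(rbind, lapply(terms, function(tm) {
    f <- (coefs[[tm]] / ses[[tm]])^2
    data.frame(term = tm, estimate = coefs[[tm]], se = ses[[tm]],
               F = f, ndf = 1, ddf = ddf,
               p = pf(f, 1, ddf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
}

# Scale-invariant separation heuristic: a fixed effect shifting the logit
# by more than ~12 per predictor sd, an exploding standardized SE, or
# fitted probabilities pinned at 0/1 all indicate a separated (or
# quasi-separated) binary response.
detect_separation <- function(fitted, coefs, ses, xsd) {
  if (any(!is.finite(coefs)) || any(!is.finite(ses))) return(TRUE)
  terms <- intersect(names(coefs), names(xsd))
  sc <- xsd[terms]
  sc[sc == 0] <- 1
  any(abs(coefs[terms]) * sc > 12) || any(ses[terms] * sc > 30) ||
    all(fitted > 0.999) || all(fitted < 0.001)
}

#' Binary (logit) mixed model with pair-style random intercept
#'
#' The shared fitting engine of [winner_model()] and [agreement_model()].
#' Fits `response ~ predictors (+ round + predictor:round) + (1 | group)`
#' with `lme4::glmer`; round enters as a numeric covariate so every term
#' carries one numerator df. When interactions with round are requested
#' they are tested first and, if none reaches `alpha`, the simple-effects
#' model without them is refit and reported (the interaction p-values are
#' kept in `interaction_tests`). Per-term Wald F-type tests use a
#' between-within denominator df. If the response separates, the model is
#' refit as a Firth-penalized fixed-effects logistic regression and
#' flagged.
#'
#' @param records data.frame of per-group per-round rows.
#' @param response name of the 0/1 response column.
#' @param predictors character vector of predictor columns.
#' @param group grouping (random intercept) column.
#' @param round_var optional numeric round column; `NULL` to omit.
#' @param interactions test predictor-by-round interactions first.
#' @param alpha threshold for dropping the interaction block.
#' @return list of class `paired_model_fit`: `coefficients`,
#'   `random_effect_variance`, `term_tests`, `interaction_tests`,
#'   `n_obs`, `n_groups`, `n_dropped`, `converged`, `separation`,
#'   `fallback`, `collinearity`.
#' @export
outcome_glmm <- function(records, response, predictors,
                         group = "pair_id", round_var = "round_index",
                         interactions = !is.null(round_var), alpha = 0.05) {
  cols <- c(response, predictors, group, round_var)
  stopifnot(all(cols %in% names(records)))
  keep <- complete.cases(records[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  df <- records[keep, , drop = FALSE]
  df[[response]] <- as.numeric(df[[response]])
  if (nrow(df) < length(predictors) + 3)
    stop("too few complete rows to fit the model")
  # drop constant predictors (inestimable), flag them
  const <- predictors[vapply(predictors, function(p)
    sd(df[[p]]) == 0, logical(1))]
  predictors <- setdiff(predictors, const)
  coll <- list(max_abs_r = NA_real_, flagged = FALSE)
  if (length(predictors) >= 2) {
    cm <- abs(cor(df[, predictors, drop = FALSE]))
    diag(cm) <- 0
    coll <- list(max_abs_r = max(cm), flagged = max(cm) >= 0.4)
  }

  base_terms <- predictors
  if (!is.null(round_var)) base_terms <- c(base_terms, round_var)
  fit_one <- function(terms) {
    fml <- stats::reformulate(c(terms, sprintf("(1 | %s)", group)),
                              response = response)
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = df, family = binomial,
                  control = lme4::glmerControl(optimizer = "bobyqa"))))
    co <- lme4::fixef(fit)
    se <- suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit)))))
    names(se) <- names(co)
    # converged = the optimizer itself succeeded; lme4's post-hoc gradient
    # checks fire routinely on near-singular random effects and are kept
    # as a separate message count rather than a failure flag
    list(fit = fit, coef = co, se = se,
         fitted = stats::fitted(fit),
         xsd = apply(stats::model.matrix(fit), 2, sd),
         revar = unname(as.numeric(lme4::VarCorr(fit)[[group]])),
         converged = isTRUE(fit@optinfo$conv$opt == 0),
         n_check_messages = length(fit@optinfo$conv$lme4$messages))
  }

  interaction_tests <- NULL
  used_interactions <- FALSE
  if (interactions && !is.null(round_var) && length(predictors) > 0) {
    iterms <- paste0(predictors, ":", round_var)
    full <- tryCatch(fit_one(c(base_terms, iterms)), error = function(e) NULL)
    if (!is.null(full) &&
        !detect_separation(full$fitted, full$coef, full$se, full$xsd)) {
      tt <- wald_term_tests(full$coef, full$se,
                            nrow(df), length(unique(df[[group]])))
      interaction_tests <- tt[tt$term %in%
                                c(iterms, paste0(round_var, ":", predictors)), ,
                              drop = FALSE]
      if (nrow(interaction_tests) > 0 && any(interaction_tests$p < alpha)) {
        used_interactions <- TRUE
        m <- full
        terms_used <- c(base_terms, iterms)
      }
    }
  }
  if (!used_interactions) {
    terms_used <- if (length(base_terms)) base_terms else "1"
    m <- fit_one(if (length(base_terms)) base_terms else character(0))
  }

  separation <- detect_separation(m$fitted, m$coef, m$se, m$xsd)
  fallback <- NA_character_
  if (separation) {
    X <- stats::model.matrix(
      stats::reformulate(if (length(base_terms)) terms_used else "1"), df)
    fl <- firth_logistic(X, df[[response]])
    m$coef <- fl$coef
    m$se <- fl$se
    m$revar <- NA_real_
    m$converged <- fl$converged
    fallback <- "firth_penalized_fixed_effects"
  }

  tt <- wald_term_tests(m$coef, m$se, nrow(df), length(unique(df[[group]])))
  structure(list(
    coefficients = data.frame(term = names(m$coef), estimate = unname(m$coef),
                              se = unname(m$se), stringsAsFactors = FALSE),
    random_effect_variance = m$revar,
    term_tests = tt,
    interaction_tests = interaction_tests,
    interactions_kept = used_interactions,
    dropped_constant = const,
    n_obs = nrow(df), n_groups = length(unique(df[[group]])),
    n_dropped = n_dropped,
    converged = m$converged, separation = separation, fallback = fallback,
    collinearity = coll), class = "paired_model_fit")
}

#' @export
print.paired_model_fit <- function(x, ...) {
  cat(sprintf("<paired_model_fit> n = %d obs, %d groups (%d dropped)%s%s\n",
              x$n_obs, x$n_groups, x$n_dropped,
              if (x$separation) " [SEPARATION: Firth fallback]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$term_tests, row.names = FALSE)
  invisible(x)
}

# Reshape a feature table (one row per whistler-round) into per-round
# difference records focal - partner (signed) or |A - B| (absolute).
difference_records <- function(features, focal_by_pair = NULL,
                               features_used = .FEATURES) {
  key <- interaction(features$pair_id, features$round_index, drop = TRUE)
  rows <- lapply(split(features, key), function(g) {
    if (nrow(g) != 2) return(NULL)
    g <- g[order(g$channel), , drop = FALSE]
    focal <- if (is.null(focal_by_pair)) "A"
             else focal_by_pair[[as.character(g$pair_id[1])]]
    i_f <- match(focal, g$channel); i_p <- 3 - i_f
    out <- data.frame(pair_id = g$pair_id[1],
                      round_index = g$round_index[1],
                      focal = focal, winner = g$winner[1],
                      agreement = g$agreement[1], stringsAsFactors = FALSE)
    for (f in features_used) {
      out[[paste0("d_", f)]] <- g[[f]][i_f] - g[[f]][i_p]
      out[[paste0("ad_", f)]] <- abs(g[[f]][1] - g[[f]][2])
    }
    out
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Which acoustic differences predict who wins a round
#'
#' For each pair one focal individual is drawn once (seeded); the response
#' is whether the focal individual won the round, and the predictors are
#' the focal-minus-partner differences in the acoustic features, plus
#' round number. Only resolved competitive rounds enter. Fitting,
#' interaction screening and Wald tests follow [outcome_glmm()].
#'
#' @param features a [feature_table()] data.frame (needs `winner`).
#' @param seed seed for the focal draw.
#' @param features_used which of the seven features to include.
#' @return a `paired_model_fit` (predictor terms are prefixed `d_`).
#' @export
winner_model <- function(features, seed = 1,
                         features_used = .FEATURES) {
  f <- features[features$condition == "competitive" &
                  !is.na(features$winner), , drop = FALSE]
  if (nrow(f) == 0) stop("no resolved competitive rounds")
  pairs <- unique(as.character(f$pair_id))
  focal <- with_seed(seed,
    setNames(sample(c("A", "B"), length(pairs), replace = TRUE), pairs))
  rec <- difference_records(f, focal_by_pair = focal,
                            features_used = features_used)
  rec$outcome <- as.integer(rec$winner == rec$focal)
  fit <- outcome_glmm(rec, "outcome", paste0("d_", features_used))
  fit$focal <- focal
  fit
}

#' Which acoustic asymmetries predict reaching an agreement
#'
#' Response: did the round end in an agreement (exactly one claimant and
#' the loser judged the split fair). Predictors: the absolute
#' between-partner differences in the acoustic features, plus round
#' number. All competitive rounds with a defined agreement flag enter.
#'
#' @param features a [feature_table()] data.frame (needs `agreement`).
#' @param features_used which features to include.
#' @return a `paired_model_fit` (predictor terms are prefixed `ad_`).
#' @export
agreement_model <- function(features, features_used = .FEATURES) {
  f <- features[features$condition == "competitive" &
                  !is.na(features$agreement), , drop = FALSE]
  if (nrow(f) == 0) stop("no competitive rounds with an agreement flag")
  rec <- difference_records(f, features_used = features_used)
  rec$agreement <- as.integer(as.logical(rec$agreement))
  outcome_glmm(rec, "agreement", paste0("ad_", features_used))
}

#' Are listener designations better than chance?
#'
#' Intercept-only binomial mixed model for correct/incorrect winner
#' designation with crossed random intercepts for listener and dialog;
#' the intercept's Wald test against logit(0.5) = 0 is the headline
#' statistic. A pooled-count [binomial_z_test()] is reported as a
#' model-free cross-check, along with per-dialog proportions. With a
#' single dialog the dialog variance is inestimable and that random
#' effect is dropped (flagged); if responses separate (e.g. everyone
#' correct) the proportion and exact binomial test still stand and the
#' fit is flagged.
#'
#' @param responses data.frame as from [simulate_listeners()]: columns
#'   `listener_id`, `dialog_id`, `correct` (logical or 0/1).
#' @return list of class `listener_concordance` with `intercept_test` (a
#'   `wdg_test`, statistic named "t"), `pooled` (proportion, k, n),
#'   `z_check` (binomial cross-check), `per_dialog`,
#'   `random_effect_variances`, and flags.
#' @export
listener_concordance <- function(responses) {
  stopifnot(all(c("listener_id", "dialog_id", "correct") %in%
                  names(responses)))
  n_listeners <- length(unique(responses$listener_id))
  n_dialogs <- length(unique(responses$dialog_id))
  if (n_listeners < 2) stop("need >= 2 listeners")
  y <- as.numeric(responses$correct)
  k <- sum(y); n <- length(y)
  per_dialog <- aggregate(y, list(dialog_id = responses$dialog_id), mean)
  names(per_dialog)[2] <- "prop_correct"
  single_dialog <- n_dialogs < 2

  fml <- if (single_dialog) correct_ ~ 1 + (1 | listener_id)
         else correct_ ~ 1 + (1 | listener_id) + (1 | dialog_id)
  df <- data.frame(correct_ = y, listener_id = responses$listener_id,
                   dialog_id = responses$dialog_id)
  separation <- k == 0 || k == n
  est <- se <- NA_real_; revars <- NULL; converged <- NA
  if (!separation) {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = df, family = binomial,
                  control = lme4::glmerControl(optimizer = "bobyqa"))))
    est <- unname(lme4::fixef(fit)[1])
    se <- suppressWarnings(sqrt(as.matrix(stats::vcov(fit))[1, 1]))
    revars <- vapply(lme4::VarCorr(fit), function(v) as.numeric(v[1]),
                     numeric(1))
    converged <- isTRUE(fit@optinfo$conv$opt == 0)
    separation <- !is.finite(se) || se > 50 || abs(est) > 15
  }
  tstat <- if (separation) NA_real_ else est / se
  pval <- if (separation) NA_real_ else 2 * pnorm(-abs(tstat))
  notes <- paste0(
    if (single_dialog) "single dialog: dialog random effect dropped; " else "",
    if (separation) "separation: intercept inestimable, use exact z_check; "
    else "")
  structure(list(
    intercept_test = new_test_result("glmm_intercept", tstat, "t", pval, n,
                                     "two_sided", notes,
                                     estimate = est, se = se),
    pooled = list(k = k, n = n, proportion = k / n),
    z_check = binomial_z_test(k, n, 0.5, side = "greater"),
    per_dialog = per_dialog,
    random_effect_variances = revars,
    n_listeners = n_listeners, n_dialogs = n_dialogs,
    single_dialog = single_dialog, separation = separation,
    converged = converged), class = "listener_concordance")
}

#' @export
print.listener_concordance <- function(x, ...) {
  cat(sprintf("listener concordance: %d/%d correct (%.1f%%)\n",
              x$pooled$k, x$pooled$n, 100 * x$pooled$proportion))
  print(x$intercept_test)
  print(x$z_check)
  invisible(x)
}
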