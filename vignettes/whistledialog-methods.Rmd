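---
title: "Models and methods behind whistledialog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind whistledialog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whistledialog)
```

## The problem

Two people, acoustically isolated from each other, negotiate who gets a
reward using nothing but whistle sounds — no words, no gestures. Each
one-minute competitive round ends with a claim ("I won", signalled by a
final whistle), and the loser later judges whether the split was fair.
Naive third-party listeners can then be asked, from audio alone, who won.

`whistledialog` implements the full analysis chain for such two-channel
whistle dialogs:

1. **Event detection** — amplitude-envelope extraction of discrete
   whistles from each channel (the pulse-train-analysis analog).
2. **Utterance segmentation** — maximal runs of one whistler's whistles
   uninterrupted by the partner.
3. **Features** — seven per-whistler, per-round acoustic variables:
   mean loudness, mean duration, whistle count, mean turn-taking gap,
   overlap proportion, and the two *positional accentuation* measures.
4. **Statistics** — paired Wilcoxon comparisons of competitive versus
   non-competitive rounds, binomial mixed models for round outcome and
   agreement, an intercept-only crossed-random-effects model for
   listener designation, and a binomial test against chance.
5. **Synthesis** — a seeded generator of whole dialogs with ground-truth
   winner labels, accentuation-manipulated playback construction, and
   simulated listener judgments, so every stage is testable without any
   field recordings.

## Key definitions and conventions

**Utterance.** A maximal sequence of one channel's whistles without
partner interruption. The operative rule is onset-based: a partner onset
strictly between two same-channel onsets terminates the current
utterance; a partner whistle that starts during the tail of a run's last
whistle also terminates it. With events sorted by onset this reduces to
grouping consecutive same-channel runs, and the package cross-checks the
streaming implementation against a brute-force interruption scan in its
tests. Exactly simultaneous onsets are ordered A before B; near ties keep
their onset order (a windowed tie rule would break the equivalence
between run-grouping and onset comparisons).

**Turn-taking gap.** For each channel switch, responder onset minus the
previous speaker's last offset. Negative "gaps" are *overlaps* and are
counted by the separate overlap variable, not clamped to zero: intervals
are half-open `[onset, offset)`, and a whistle overlaps iff its onset
falls inside a partner whistle.

**Accentuation.** For every utterance with at least two whistles:
first-whistle value minus the mean of the following whistles' values
(duration in seconds, loudness in amplitude units); the feature is the
mean of these per-utterance differences. Single-whistle utterances carry
no positional information and are skipped; if none qualifies the feature
is missing, never zero. A positive duration accentuation — stressing the
utterance-initial whistle — is the prosodic signature of contest winners
that the whole analysis revolves around.

**Round outcome.** A round is *resolved* iff exactly one whistler
claimed; it is an *agreement* iff, additionally, the loser judged the
reward distribution fair. Claims are experimenter-recorded metadata, not
inferred from audio.

**Missingness.** Missing features propagate as missing; every averaging
step reports its effective n. Silent channels or rounds never fabricate
zeros.

## The detector

Detection is deliberately minimal, matching what the analysis needs
(duration, loudness, timing — no spectral content): rectify, smooth with
a 5 ms moving average, open an event when the envelope rises to 10% of
the channel's peak envelope, close it at 5% (hysteresis), merge events
closer than 30 ms, drop events shorter than 20 ms. The thresholds are
relative, so detection is invariant to recording gain. The reference
pulse-train settings used on the original recordings were never
published; these defaults are this package's choices, all overridable via
`detector_params()`.

Loudness is measured in envelope units. The synthetic renderer produces
sine bursts, whose rectified-smoothed envelope converges to `2/pi` times
the burst amplitude (the render frequency is deliberately incommensurate
with the sample rate, otherwise phase-locked sampling biases this
constant); round-trip tests therefore compare amplitudes after dividing
by `2/pi`, with a 5% allowance for edge effects. Whether "loudness" means
per-whistle mean or peak amplitude is a configuration switch
(`loudness_measure`); the default is the mean.

## The statistical battery

**Paired signed-rank test.** The reported statistic is the centered
`S = W+ − m(m+1)/4` over the `m` nonzero differences (positive `S` means
the first series is larger), with zero differences dropped and tied
absolute differences mid-ranked. For `m ≤ 25` the p-value is exact — the
full sign-flip null distribution is built by convolution over the
(possibly tied) ranks — and beyond that a tie-corrected normal
approximation is used. Tests verify the exact path against brute-force
`2^m` enumeration and the classical no-tie distribution.

**Binomial Z test.** `Z = (k/n − p0) / sqrt(p0(1−p0)/n)` without
continuity correction; this convention reproduces the study's printed
`Z = 2.19, p = 0.014` for 21 of 30 listeners. The exact binomial tail is
always reported alongside (`exact_p`). Note the uncorrected normal tail
tracks the exact *mid-P* tail (within 0.02 in the moderate-deviation
regime); against the plain exact tail it can differ by up to ~0.07 at
small deviations — one reason the exact value is carried along.

**Outcome and agreement models.** Binomial (logit) mixed models with a
pair random intercept, fit by `lme4::glmer`. For the winner model one
focal individual per pair is drawn once (seeded); the response is whether
the focal individual won, and predictors are focal-minus-partner feature
differences plus round number; only resolved rounds enter. The agreement
model uses absolute between-partner differences on all competitive rounds
with a defined agreement flag. Round number enters as a numeric covariate
so every term carries one numerator df. Predictor-by-round interactions
are tested first and dropped when none is significant; per-term Wald
F-type tests use a between-within denominator df
(`n_obs − n_groups − (n_fixed − 1)`). A pairwise-correlation collinearity
screen (|r| ≥ 0.4) is reported. If the response separates — flagged by
scale-invariant standardized-coefficient/SE heuristics — the model falls
back to a Firth-penalized fixed-effects logistic regression, clearly
flagged; small binary mixed models separate easily and silent garbage
coefficients would be worse than a penalized approximation without the
random effect.

**Listener concordance.** An intercept-only binomial mixed model with
crossed random intercepts for listener and dialog; the intercept's Wald
test against `logit(0.5) = 0` answers "better than chance?". With a
single dialog the dialog variance is inestimable and that term is
dropped (flagged). A pooled-count binomial Z test and per-dialog
proportions are always reported as model-free cross-checks.

The `converged` flag of the mixed models reflects the optimizer status;
lme4's post-hoc gradient checks, which fire routinely on near-singular
random effects in simulation, are reported as a message count instead.

## The synthetic world

`generate_dialog()` alternates utterances between channels: utterance
lengths are drawn from an exponentially tilted discrete uniform on 3–8
(tilted per role so the winner:loser whistle-rate ratio is 41:36),
whistle durations and loudness are log-normal, turn gaps gamma, and with
a configurable probability a turn starts *before* the partner's last
whistle ends. Each utterance-initial whistle receives a role-dependent
duration and loudness delta, drawn once per whistler-round.

Defaults are the stated world of the original study's competitive
rounds, in its units: follower duration 0.34 s and loudness 0.12 so the
overall per-condition means land at the printed 0.36 s / 0.13; winner
and loser accent deltas 0.14 / 0.07 s and 0.03 / 0.04 units; gap mean
1.4 s; overlap 4%; non-competitive rounds use 0.23 s / 0.09 units,
symmetric 0.10 s accents, 1.8 s gaps, symmetric rates. Three calibration
choices deserve flagging:

* The source's numbers are not all jointly satisfiable: its pooled
  first-vs-following means (0.35 vs 0.24 s) are inconsistent with its
  per-condition means plus accentuations (0.36 mean with 0.11 accent
  implies followers near 0.34), and its condition-level loudness accent
  (0.05) differs from its winner/loser split (0.03/0.04). The generator
  follows the per-condition/per-role table throughout, since that is
  what the models consume. Consequences: the condition-level contrasts
  in loudness accentuation and whistle count are real (and often
  significant) in synthetic data even though the study reported them as
  null.
* `accent_delta_sd = 0.06 s` — the between-round spread of the accent
  delta — is calibrated once so the winner model's accent term lands at
  the study's printed F ≈ 10 at its design scale (45 pairs × 3 rounds).
  With zero spread the accent difference separates the outcome
  perfectly, which no real dataset shows.
* Whistle loudness is clamped to `[0.5, 2.5] × loudness_mean` and
  overlapped onsets avoid 20 ms guard bands at the partner whistle's
  edges: unbounded draws occasionally produce whistles invisible to a
  10%-of-peak detector, or overlaps below the detector's ~5 ms boundary
  resolution, making the audio round trip ill-posed rather than wrong.
  Both bounds are also physically sensible for toy whistles.

Absolute whistle rates are emergent (utterance lengths × timing), and
come out somewhat above the study's 37 per minute (~45–55); only the
winner:loser contrast is calibrated. `generate_session()` adds the
session structure — 3 min non-competitive, three 1-min competitive
rounds, 2 min non-competitive — and samples claims and fairness at the
study's marginal rates (88% resolved, 82% judged fair, unresolved rounds
splitting 7:5 between double and absent claims). An optional
logit-linear link ties fairness to the measured between-partner accent
gap for simulation studies; it is off by default so the marginal rates
stay put.

What a green test on this world does **not** establish: robustness to
recording noise, reverberation or channel cross-talk (detection is
thresholding on clean audio); human behavioral correlations between
features (features are generated independently given role); or any claim
about the original recordings, which were never deposited — the study's
real-data statistics are pattern targets only.

**Listener simulation** draws independent Bernoulli designations at a
fixed concordance probability (default 0.7, the observed regime) with
confidence drawn independently — deliberately the simplest model
consistent with the reported marginals, including the observation that
confidence did not predict accuracy.

**Playback construction** permutes each 3–8-whistle utterance so the
longest whistle sits first (high accentuation) or at position
`floor(n/2)` counting from zero ("middle"; the source never defines
middle for even lengths, this package fixes the floor convention, with
ties going to the earliest original position). The two variants of an
utterance are permutation-identical — same whistles, same total
duration — differing only positionally. Natural-dialog playback
selection requires an agreement round whose whistlers differ by less
than 10% in whistle count and mean duration; the unstated denominator is
fixed as the symmetric relative difference `|a−b| / mean(a,b)` with
strict inequality, followed by loudness equalization (each channel
scaled so both channel means equal their grand mean — which preserves
duration accentuation exactly and scales loudness accentuation by the
channel factor).

## Numerical and degenerate-input choices

* Empty event lists segment to empty utterance lists, not errors;
  channels with no whistles yield missing features with `n_whistles = 0`.
* An all-zero waveform detects zero events; invalid detector parameter
  combinations (hysteresis ≥ threshold, etc.) error at construction.
* All-zero paired differences give `S = 0, p = 1`; constant predictors
  are dropped from models and named in the fit object; constant inputs
  to the rank correlation are flagged, not errored.
* Seeds: every stochastic entry point takes one integer seed; sub-draws
  derive from it, and the caller's RNG state is restored afterwards.
* Event-table CSV is the interchange format (one row per whistle with
  round metadata); round length survives via an extra
  `round_duration_s` column, else it is inferred as the last offset
  rounded up to the next second.

## Known limitations

* No spectral features: pitch prosody is out of scope by design.
* The detector assumes acoustically isolated channels; no cross-talk
  cancellation.
* The exact estimation machinery of the original mixed models is
  unknown; the lme4 + Wald/between-within convention here is a
  defensible stand-in, not a claimed equivalence.
* Firth fallback drops the random intercept; its term tests are
  approximate under strong pair heterogeneity.
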