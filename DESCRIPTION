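Package: whistledialog
Title: Analysis and Simulation of Non-Verbal Whistle Dialog Contests
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-channel whistle dialogs in which two
    participants negotiate a contest outcome using only whistle sounds.
    Detects whistle events from audio by amplitude-envelope thresholding,
    segments each channel into utterances (maximal whistle runs without
    partner interruption), computes per-round acoustic features including
    first-whistle duration and loudness accentuation, and runs the contest
    statistics: paired Wilcoxon signed-rank comparisons, binomial tests
    against chance, and binomial mixed models for round outcome, agreement
    and third-party listener designation. Includes a seeded synthetic
    dialog generator with ground-truth winner labels, accentuation playback
    construction, and simulated listener judgments so the whole pipeline is
    testable without field recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
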