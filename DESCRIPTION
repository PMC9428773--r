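Package: breathphase
Title: Real-Time Breathing-Phase Detection from Audio with Paced-Breathing Session Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short (0.195 s) audio frames into exhalation,
    inhalation and nonbreathing phases using a log-mel front end, a
    fixed-length audio embedding, a small trainable softmax head and a
    soft-voting ensemble. Provides the ordered threshold decision policy,
    an exhalation-hold smoothing heuristic for streamed output, a paced
    breathing session simulator with biofeedback scoring, interval label
    track handling with two-rater merging and Cohen's kappa, evaluation
    metrics (per-class and multi-class balanced accuracy, ROC/AUC,
    Bland-Altman limits of agreement), and a seeded synthetic breathing
    audio generator for end-to-end pipeline verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
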