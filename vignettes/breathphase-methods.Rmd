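---
title: "Breathing-phase detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breathing-phase detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathphase)
```

## The problem

Breathing-guided biofeedback needs a detector that, several times per
second, answers: is the user exhaling, inhaling, or neither? The
exhalation class covers two acoustically distinct subtypes — the
airborne *acoustic* exhalation sound and the wind-like *airflow*
disturbance produced when breath hits the microphone membrane — which
the detector must map to a single exhalation call. Everything else,
including silence, is *nonbreathing*.

`breathphase` implements this as a frame classifier plus the decision
and smoothing layers a real-time deployment needs, and pairs it with
evaluation and simulation machinery so every stage can be tested
offline against synthetic ground truth.

## Pipeline

**Framing.** Audio is resampled to 16 kHz mono (polyphase band-limited
resampling via `signal::resample`; stereo is averaged, the neutral
choice). The detector's atomic input is a 0.195 s frame = 3120
samples — short enough that feedback feels immediate, long enough to
carry spectral signal. Batch processing uses gapless non-overlapping
frames; streamed detection uses the most recent 3120 samples at a
configurable tick rate (default 30 Hz). Trailing remainders shorter
than one frame are dropped, never padded: padding would fabricate
signal. Both modes are exposed because a deployed detector running
"every frame" at ~30 Hz is most naturally a sliding window, while
labeled datasets are built from gapless frames; `detect_clip()`
defaults to gapless frames for evaluation and offers `mode =
"sliding"` for stream emulation.

**Front end.** Each frame is tiled five-fold to 15,600 samples
(0.975 s), the minimum input of the pretrained audio-event network the
head was designed around; tiling rather than constant-padding keeps
distinct sounds maximally distinct from silence. The log-mel
representation uses a 400-sample (25 ms) periodic Hann window,
160-sample (10 ms) hop, FFT length 512 (the next power of two above
the window — the source network's convention), *magnitude*
spectrogram, 64 HTK-style triangular mel filters over 125–7500 Hz, and
`log(S + 0.001)`. No edge padding is applied ("valid" framing), so a
15,600-sample input yields exactly `floor((15600 - 400)/160) + 1 = 96`
time steps and every cell is bounded below by `log(0.001)`, with
equality exactly on silence. Window function, FFT size and
magnitude-vs-power are conventions of that front end, not published
constants; they are centralised so an adapter to the real network can
override them.

**Embedding.** The classifier head consumes 1024-dimensional
embeddings through a pluggable backend contract. The shipped
*surrogate* backend is a deterministic feature map: per-mel-band mean,
standard deviation, maximum and mean absolute first difference (256
features), expanded to 1024 dimensions by a fixed seeded Gaussian
random projection and a tanh squashing. It is not a learned model and
makes no claim to the real network's representational power; it exists
so the entire pipeline — training, selection, thresholding, smoothing,
scoring — runs and is testable fully offline. An adapter slot for the
real pretrained network fails loudly when its external assets are
absent, never silently substituting the surrogate.

**Head and ensemble.** The trainable component is deliberately small:
dense 1024 → 32 with swish (`x·sigmoid(x)`), then 32 → 3 with softmax.
Training is mini-batch (32) Adam — lr 0.001, β₁ 0.9, β₂ 0.999, the
optimizer's canonical defaults, exposed in `training_config()` — on
categorical cross-entropy, with early stopping at patience 10 and
restoration of the best-validation-loss weights. `max_epochs`
defaults to 100, comfortably bracketing the 5–10 epochs at which this
head typically begins to overfit. No class balancing is applied: the
nonbreathing class is deliberately dominant so the detector is
conservative about calling breathing in noisy surroundings. Many
candidate heads are trained from distinct derived seeds (default pool
20, configurable; selection logic is what matters, not pool size) and
the 3 with lowest validation loss form an equal-weight soft-voting
ensemble; probabilities are averaged before thresholding, since the
decision thresholds are defined on prediction probabilities.
Initialisation is seeded Glorot-uniform; with fixed seeds training is
bit-reproducible on a given platform.

**Decision policy.** The ordered threshold rule checks exhalation
first: exhalation if `p_ex ≥ τ_ex`, else inhalation if `p_in ≥ τ_in`,
else nonbreathing, with `τ = 0.3` for both breathing classes by
default — a value chosen (in the original deployment) by inspecting
TPR-versus-threshold curves for balance between the classes.
Comparison is inclusive so τ = 1 remains attainable by certainty-1
predictions. `youden_optimal_threshold()` implements the alternative:
per-class thresholds maximising J = sensitivity + specificity − 1,
evaluated at every distinct observed score plus {0, 1} (J is piecewise
constant in between), ties to the smallest threshold.

**Exhalation hold.** Feedback quality hinges on exhalation stability,
and exhalation precision is typically much higher than its
sensitivity. The hold heuristic therefore forces the output to
exhalation for 300 ms after every raw exhalation call, resetting on
each new one. The hold comparison is strict (`t < hold_until`): a call
exactly at expiry uses the raw phase. The heuristic operates on the
policy's phase calls, not on probabilities, and is defined on explicit
timestamps so it is agnostic to tick cadence. It can only add
exhalation calls — it never converts an exhalation to anything else —
so exhalation recall cannot decrease, at the cost of specificity.

**Session scoring.** Guidance patterns follow
inhale–pause–exhale–pause. The base pattern is 4-1-5-0 s at 6 BPM; for
other rates the pauses stay (1, 0) and the remaining `60/bpm − 1`
seconds are split 4:5 between inhalation and exhalation — the unique
linear rule consistent with both published patterns (6 BPM → 4-1-5-0;
7 BPM → 3.37-1-4.21-0). The feedback loop is an Euler simulation at
the tick rate: during guided exhalations that the detector (after the
hold) also calls exhalation, speed grows linearly at `accel` up to
`max_speed`; otherwise it decays exponentially (`decay_rate`) to
`base_speed`. The defaults (1, 2, 4, 1 in units/s and s⁻¹) are
artifact choices — the deployed app describes its dynamics only
qualitatively — and are config-exposed and excluded from any
quantitative claim. "Breathing accuracy" is operationalised as
guided-exhalation coverage: the fraction of guided-exhalation ticks
whose smoothed detection is exhalation. This is one defensible
concretisation of an informally described in-app score; it is
documented prominently because it is a definition, not a reproduction.

## Annotation handling

Label tracks are ordered half-open `[start, end)` intervals over
`{exhalation_acoustic, exhalation_airflow, inhalation, nonbreathing,
unclear}`; unlabeled time is implicitly nonbreathing. Merging two
raters pairs intervals by temporal overlap; boundary pairs ≤ 200 ms
apart are averaged, larger differences are flagged for manual
inspection (never auto-resolved), and class conflicts — including
intervals only one rater marked — become `unclear`, the conservative
choice that never invents agreement. Frame-grid projection assigns
each 0.195 s frame its majority-overlap label (subtypes collapsed to
exhalation), masks any frame touching an `unclear` interval, and
breaks exact ties by exhalation > inhalation > nonbreathing. Cohen's κ
is computed on that frame grid over the three collapsed classes; the
granularity choice matters, which is why κ values are reported with
the grid stated and are not treated as comparable across granularities.

## Metrics

Per-class metrics are one-vs-rest: precision, recall/sensitivity,
specificity, F1, and balanced accuracy = (recall + specificity)/2.
Zero-denominator ratios surface as `NaN` with a warning, never
silently as 0. Two multi-class aggregates are provided because both
appear in the literature: the mean of per-class recalls (Kelleher et
al.) and the mean of per-class balanced accuracies (Urbanowicz &
Moore). ROC curves sweep the distinct observed scores one-vs-rest with
trapezoidal AUC (equal, with ties handled, to the rank-sum
probability); Bland–Altman agreement uses sample-SD limits
`mean ± 1.96·SD`. Internally everything is full precision; rounding to
the 2 decimals of published tables happens only at presentation.

## Synthetic data: what it shows and what it cannot

No breathing recordings ship with the package, so verification rests
on a seeded generator that emulates the acoustic *structure* the
detector assumes, deliberately exaggerated for separability:

- inhalation: quiet band-passed noise (300–2000 Hz), RMS 0.05;
- acoustic exhalation: louder broadband noise (100–6000 Hz) with a
  raised-cosine onset/offset envelope, RMS 0.15;
- airflow exhalation: high-amplitude low-passed noise (< 250 Hz
  cutoff; ≥ 80 % of spectral energy below 500 Hz by construction),
  RMS 0.4;
- pauses: ambient noise (RMS 0.002), optionally carrying tone, chirp
  or noise-burst events;
- cycles follow `pattern_for_bpm()` with Gaussian boundary jitter
  (SD 0.05 s default), and the acoustic/airflow exhalation mix
  defaults to the 418:4574 ≈ 8.4 % airflow share of the detector's
  training composition.

All randomness flows from one config seed through a documented
derivation (`stream k` of seed `s` seeds its RNG with
`(s·10007 + k) mod (2³¹−1)`), so any generated artifact is
reproducible from its config alone.

Because the archetypes are spectrally disjoint, end-to-end recovery —
training the surrogate pipeline on 300 frames per class and scoring a
fresh synthetic session at multi-class balanced accuracy ≥ 0.90 —
verifies the *pipeline*, not the science of real breathing audio: a
failure indicates a wiring defect, while success says nothing about
performance on real microphones, noise suppression in Bluetooth
headsets, silent breathers, or the acoustic overlap between quiet
inhalations and silence that makes the real problem hard. Published
deployment-scale results on real recordings are correspondingly *not*
claims this package re-establishes; what it reproduces exactly are the
metric identities, pattern arithmetic and policy semantics, each
checked in the test suite.

## Numerical choices and degenerate inputs

- Frame/tiling arithmetic is integer-exact (3120 × 5 = 15,600).
- `resample_to_16k` trims/pads the polyphase output by at most one
  sample to the exact `round(n·16000/rate)` length, and clamps to
  `[-1, 1]`.
- Sub-frame clips yield zero frames (batch) or an empty stream
  (sliding), not errors; zero-length audio is a valid empty clip.
- Early stopping counts *consecutive* non-improving epochs; patience 0
  stops at the first one. Ensemble selection ties break by candidate
  index.
- Youden and ROC sweeps use inclusive `score ≥ τ`; candidate sets are
  finite by piecewise-constancy, so no grid resolution parameter
  exists to tune.
- The test suite and examples run at reduced scale (hundreds of
  frames, 60 s sessions, candidate pools of 5–20) — sizes chosen as
  the smallest at which every selection/aggregation mechanism is still
  genuinely exercised.

## Known limitations

- The surrogate embedding is a fixed feature map; its 1024-dim width
  matches the real backend's interface, not its capacity.
- The generator does not model device microphones, codec/noise
  suppression, room acoustics, or psychoacoustic realism.
- The two-rater merge resolves class conflicts to `unclear`
  unconditionally; it does not implement per-case adjudication.
- The in-app accuracy score and boat dynamics are artifact
  definitions, suitable for simulation studies of the feedback loop's
  logic, not for quantitative comparison with any deployed app.
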