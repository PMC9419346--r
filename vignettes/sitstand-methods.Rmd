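---
title: "Methods: posture classification and sedentary bout analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture classification and sedentary bout analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models, parameter
choices, numerical conventions and limitations. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Measurement setting and data model

Two devices are modelled. A thigh-worn inclinometer reports posture as an
ordered, contiguous list of events (sitting/lying vs upright), with the
constraint that a new posture must persist at least 10 s to be registered.
A hip-worn accelerometer reports (a) raw triaxial acceleration at 30 Hz in
g units and (b) proprietary "counts" integrated per 60-s epoch. The
inclinometer is treated as ground truth; the task is to recover
posture-based sedentary measures from the hip sensor alone.

All timestamps are timezone-naive local time (devices log local time),
represented internally as UTC `POSIXct` so arithmetic never crosses DST
rules; daylight-saving transitions are out of scope. Streams claim a start
time and constant rate, so gaps are unrepresentable by construction and
parsers reject files whose timestamps are inconsistent with the declared
rate rather than repairing them.

## Pre-processing conventions

* **30 → 10 Hz** by non-overlapping 3-sample block means. Block means are
  deterministic, phase-robust, and mildly anti-aliasing; naive decimation
  would alias the ~2 Hz gait band. A trailing remainder of one or two
  samples is dropped with a message — padding would fabricate signal.
* **Per-second posture labels**: a second takes the label of the event
  covering its *start instant*, so a second beginning exactly at an event
  change belongs to the new event. This tie-break is arbitrary but
  deterministic and is exercised directly by the tests.
* **10-s epochs**: an epoch is sitting when ≥ 6 of its 10 seconds are
  sitting, otherwise non-sitting. The 10-s resolution matches the
  inclinometer's registration minimum, and the 6-of-10 majority-with-bias
  rule is the field's aggregation convention for these devices.
* **Wear masking**: evaluation uses only epochs whose full 10-s span lies
  inside the intersection of all supplied masks (accelerometer non-wear
  from counts, plus any sleep/wear masks given as inputs). Monitor clock
  drift is not corrected; the alignment API accepts a fixed offset via the
  mask intervals if a sensitivity analysis needs one.

## Non-wear detection

The Choi rule on 60-s vertical-axis counts: a minute is non-wear when it
lies in a run of at least 90 zero-count minutes, where a spike of at most
2 consecutive nonzero minutes is absorbed into the run only when flanked on
both sides by at least 30 consecutive zero-count minutes. Absorbed spike
minutes count toward the run length (so 45 zeros + 2 spike + 45 zeros is a
single 92-min non-wear block), and a spike near the recording edge without
a full 30-min zero flank is never absorbed. The implementation is run-length
based; the tests compare it minute-for-minute against an independent
window-enumeration oracle over thousands of random count streams.

## The classifier

Architecture (all sizes configurable through `model_config()`):

* input: a 10-s window of 10 Hz triaxial acceleration (100 × 3), globally
  standardized per axis with training-set mean/SD stored in the model.
  Standardization is *global*, not per-window: the constant gravity
  component encodes hip tilt, which is the posture signal, and per-window
  centering would erase it.
* convolution stack: 1-D valid convolutions with kernel 5 (0.5 s) and
  channels 32 → 64, ReLU, mean-pooling by 2 after each layer, then a
  global mean over time — one 64-dimensional feature vector per epoch.
* sequence model: a bidirectional LSTM (64 units per direction) over a
  window of 9 consecutive epochs (90 s of context), capturing how sitting
  and standing epochs occur in sequence.
* output: a 2-class softmax per epoch. The label is SIT iff the sitting
  probability is strictly greater than 0.5; exactly 0.5 is NONSIT.

The sequence length of 9 epochs is an implementation default (the context
width is not externally fixed); it is odd so each epoch has a well-defined
central position. At prediction time each epoch is predicted exactly once,
from the stride-1 sequence in which it is centred; sequences running past
the ends of the recording replicate the first/last window and the padded
outputs are discarded. This avoids any ambiguity about averaging
overlapping predictions.

Training minimizes softmax cross-entropy with Adam (learning rate 1e-3,
batches of 16 nine-epoch sequences) over non-overlapping sequences from the
training participants. After each pass, the model is evaluated on held-out
*selection* participants with the selection metric: the unweighted mean of
(a) epoch-level balanced accuracy and (b) balanced accuracy of the
sit-to-stand-transition indicator (a SIT epoch followed by a NONSIT epoch).
Equal weights are a design choice; the metric is early-stopped with
patience 5 and the best checkpoint is retained. Dropout (0.2) is applied to
the CNN features and the LSTM outputs during training only. All randomness
(initialization, shuffling, dropout) is governed by explicit seeds, and the
whole forward/backward pass is plain matrix algebra, so runs are
bit-reproducible; a finite-difference gradient check is part of the test
suite. `grid_select()` compares candidate architectures on the selection
participants and breaks metric ties toward fewer parameters.

## Bout variables

* A sedentary bout is a maximal run of SIT epochs (minimum one epoch: 10 s
  for posture labels, 1 min for the counts method). UNWORN epochs
  terminate a bout; bouts truncated by non-wear contribute their observed
  duration, with no imputation.
* A break (synonymous with a sit-to-stand transition) is a SIT epoch
  immediately followed by a NONSIT epoch, with no interruption tolerance.
  A bout ending at the series end or at non-wear is not a break.
* Usual bout duration is the duration-weighted median with the lower
  convention: sort durations ascending and return the smallest duration at
  which the cumulative sum reaches half of total sitting time. The
  nonlinear `x^n / (x^n + W50^n)` curve-fit variant found in older software
  is deliberately not the default — the weighted-median phrasing is the
  definition implemented; it always lies at or above the unweighted median.
* α is the continuous maximum-likelihood power-law exponent
  `1 + n / Σ ln(xᵢ/xmin)` with `xmin` equal to the method's minimum bout
  (10/60 min for posture labels, 1 min for counts). α is undefined (error)
  when all bouts equal `xmin`; participant-seasons where that happens are
  reported with missing α rather than a fabricated value. Least-squares
  fits on log-log histograms are biased and are not provided.
* Counts cut-point: a minute is sedentary iff its vertical counts are
  strictly below 100 cpm. The boundary minute (exactly 100) is
  non-sedentary. The legacy convention classifies *low*-count minutes as
  sedentary — this direction is what makes the comparator underestimate
  sedentary time in practice — and the threshold is configurable.
* Valid days require ≥ 480 min (8 h) of simultaneous two-monitor wear;
  participant-seasons require ≥ 3 valid days. Per-day variables
  (sedentary min, breaks, min in bouts ≥ 30 min) are averaged across valid
  days; mean/usual bout duration and α are computed on the bouts *pooled*
  across valid days, because per-day power-law fits are unstable below
  ~50 bouts. A per-day-then-average variant would be a one-line change in
  `summarize_participant_season()` but is intentionally not a flag until
  someone needs it.

## Evaluation machinery

Epoch metrics use SIT as the positive class; balanced accuracy is exactly
the mean of sensitivity and specificity, and any metric with a zero
denominator propagates as missing (never 0) and is excluded from
across-season means with the defined-n reported. Aggregation is always
per participant-season, then mean (SD) across seasons — never pooled-epoch
micro-averages.

Transition pairing matches each true sit-to-stand transition, in
chronological order, to the *earliest* unmatched predicted transition
within the lag tolerance (default 60 s, strictly: |Δ| ≤ tolerance).
Because every pairing window has the same width, this greedy order attains
the maximum one-to-one matching (the bipartite graph is convex), which
gives the estimator two properties the obvious nearest-first rule lacks:
it is symmetric under swapping predictions and truth (sensitivity and PPV
exchange), and it is monotone non-decreasing in the tolerance. The tests
verify equality with an exhaustive matching oracle on small instances.

Agreement across participant-seasons reports bias (method − truth), its
SD, MAE, MAPE (over seasons with positive truth), Spearman correlation
with average-rank ties, and Lin's concordance computed with population
(1/n) moment estimators, `2s_xy / (s_x² + s_y² + (x̄−ȳ)²)`.

## The synthetic generator

The generator is the test harness standing in for a paired two-device
study; its defaults are the study conditions everything else is tested
under.

* Posture is an alternating renewal process. Sitting bout durations follow
  a continuous power law with exponent 1.40 and `xmin` 10 s — the scale
  reported for children by inclinometer studies — truncated at
  `sit_xmax_s` (default 60 min). The truncation is not cosmetic: a power
  law with exponent 1.4 has infinite mean, so an untruncated generator
  could neither hold a target sitting fraction nor produce a stable bout
  count per day. Upright durations are lognormal (σ = 0.8) with the mean
  chosen so the long-run sitting fraction hits `p_sit_time` (default 0.62,
  giving ≈ 450 sedentary min in a 12-h wear day). Durations are quantized
  to 1 ms at generation so in-memory truth and the millisecond-precision
  events files are identical.
* The registration rule merges any event shorter than 10 s into the
  preceding registered posture (the new posture "fails to register"); the
  first event is kept regardless. The operation is idempotent and
  time-conserving.
* Raw 30 Hz acceleration is a gravity vector tilted by a posture-dependent
  hip angle (35° sitting vs 5° upright at difficulty "easy"; 15° vs 8° at
  "hard") plus Gaussian sensor noise (SD 0.01 g), a ~2 Hz stepping
  oscillation during upright seconds, and sparse 1-s fidget bursts during
  sitting. At "easy", every upright second moves and fidgets stay small,
  so 10-s windows are linearly separable by dynamic variance alone — this
  gives model tests an explicit performance floor (a variance-threshold
  oracle) that the network must beat. "hard" shrinks the tilt separation,
  makes upright movement intermittent, strengthens fidgeting and jitters
  the signal change points by up to ±2 s around the label boundaries, for
  non-saturating benchmarks.
* Counts are the deadbanded (0.05 g) dynamic deviation of the vector
  magnitude from 1 g, summed per minute and scaled; still minutes are
  exactly zero (so Choi detection is exercisable) while walking minutes
  exceed the 100 cpm cut-point. Counts are a deterministic functional of
  the raw stream.

What the generator does *not* emulate: biomechanically realistic gait or
posture transitions, device-specific count filters, monitor clock drift,
sleep, and the inclinometer's actual classification errors (its output is
taken as definitionally true). Consequently, passing the learning
benchmarks here demonstrates that the pipeline's machinery is correct and
that the architecture can learn tilt-plus-dynamics posture signatures —
it does not certify any particular accuracy on real children, where signal
overlap between postures is far larger.

## Problem sizes and numerical choices

The test suite trains on deliberately small problems: the learning
benchmark uses ten simulated participants with one 1-h wear day each
(6 train / 2 selection / 2 test, seed 7), where the easy generator's
variance oracle exceeds 0.95 balanced accuracy and the default network
reliably exceeds it; the oracle-classifier identity study uses three
participants with four 12-h days so the valid-day rules (8 h, 3 days)
operate at their real scale. Power-law recovery uses 10,000 draws.
Tolerances: exact identities (bout conservation, balanced-accuracy
arithmetic, pipeline identity) are asserted to machine precision;
stochastic recoveries use the bounds stated alongside each test
(±0.02 for α̂ on 10,000 draws, ±3 percentage points for the generated
sitting fraction). Degenerate inputs are errors, not silent values: empty
bout lists, all-`xmin` α, single-class training labels, unfitted models,
zero combined variance in the concordance.

## Known limitations

* The events-file reader targets the classic CSV events export; binary
  device containers (.gt3x, .datx) are out of scope.
* The counts synthesis is a caricature of the proprietary counts filter —
  adequate for exercising the cut-point comparator and Choi detection, not
  for calibrating counts-based cut-points.
* Training is single-threaded CPU R; it is comfortable at the sizes above
  (minutes) but not intended for hundreds of participant-weeks.
* The 100 cpm comparator's direction (sedentary below the cut-point)
  follows the legacy convention; literature that states the inequality in
  the opposite direction should be read against its own results before
  comparison.
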