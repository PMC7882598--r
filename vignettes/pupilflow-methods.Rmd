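---
title: "Modeling pupil dynamics from eye-tracking events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pupil dynamics from eye-tracking events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pupil diameter is widely used as a physiological index of arousal, cognitive
load and engagement, but most of its variance in naturalistic viewing is
*non-cognitive*: the pupillary light reflex (constriction with increasing
luminance), accommodation, and movement artifacts. pupilflow implements a
modeling strategy for separating these components when subjects watch
instructional video while an eye tracker records classified events
(fixations, saccades, blinks). A sequence model is trained to predict
near-future pupil diameter from the recent event history. Because
luminance-driven dynamics follow the stimulus and are therefore learnable,
while arousal-driven dilations are idiosyncratic and transient, the model
preferentially captures the non-cognitive part of the signal. The
*residual* — measured minus predicted diameter — is then examined as a
cognition-linked signal: its per-subject mean is correlated with
post-viewing assessment scores, and its ability to separate high from low
performers is quantified by ROC AUC against a label-permutation null.

## From event streams to prediction problems

An event stream is one subject watching one video: ordered fixations (with
screen position, duration, and pupil diameter in micrometres), saccades and
blinks. Subjects who spend more than 6% of their total recording time
blinking or fixating outside the video frame are excluded
(`quality_filter()`); the fraction is pooled over a subject's videos, since
the exclusion is a judgment about the subject, not about a single
recording.

Streams are cut into consecutive, non-overlapping blocks of 15 s (or 20 s),
anchored at the stream start, with the trailing remainder discarded
(`segment_blocks()`). The first 10 s of each block provide input features;
the unweighted mean pupil diameter over fixations in the remaining 5 s (or
10 s) is the scalar label. An event belongs to a window iff its *onset*
falls inside it — an unambiguous rule for events that straddle a boundary.
Blocks lacking a fixation in either window are dropped and counted. Blocks
are then pooled across subjects, videos and modalities and treated as
exchangeable samples.

Two labeling choices were genuinely open and are worth stating: the label
mean is unweighted (not duration-weighted), and window membership is by
onset. Both are configurable only by editing the code deliberately; they
are invariants of the protocol, not tuning knobs.

## Features

Per-fixation numeric features are position, duration, start time (relative
to the window start), optionally the pupil diameter, and the first-order
difference of each (defined as 0 at the first fixation). When the
saccade/blink channel is enabled, separate saccade and blink sequences
(positions, durations, start times, differences) are built for the tabular
models, and saccade/blink information additionally enters the recurrent
models as per-fixation covariates (preceding-saccade duration and
displacement, time since the last blink, blink count in the preceding
gap). This alignment choice — one sequence axis per block, indexed by
fixations — keeps the recurrent architecture single-stream; the vendor
formats do not dictate how the three event sequences should be interleaved,
so this is a design decision of the package.

Numeric features are z-scored with mean and population SD computed on the
*training* blocks only; zero-spread features get their SD guarded to 1.
Sequences are padded to the training-split maximum lengths with the
per-feature training mean, which is exactly 0 after normalization; test
blocks longer than the training maximum are truncated from the end with a
warning. Fixation positions are also mapped to areas of interest (AOIs):
named, half-open rectangles (instructor, slide text, slide image) defined
per video and modality. Half-open intervals plus a priority order make the
mapping total and deterministic, including on shared edges. The AOI
sequence is consumed as learned embeddings by the recurrent models and as
one-hot codes by the tabular ones.

## The model menu

`model_config()` configures one of eight predictors:

* **INPUT_MEAN** — the naive baseline: the mean input-window fixation
  diameter. Surprisingly strong, because pupil diameter is highly
  autocorrelated at the 5–15 s scale.
* **LINEAR / RIDGE / LASSO** — (penalized) linear regression on the
  flattened, padded feature vectors. The flattened design is far wider than
  the sample count, so plain least squares is rank-deficient; the LINEAR
  model uses an SVD pseudo-inverse and is reported as a reference, not
  relied upon. Ridge and lasso use glmnet with a penalty path extended to
  near-zero and the penalty chosen on the validation split.
* **RF / GBM** — random forest (ranger) and gradient boosting (xgboost)
  with conventional defaults (500 trees; learning rate 0.1, depth 3 with
  validation-based early stopping).
* **LSTM / GRU** — the package's core: two stacked bidirectional recurrent
  layers over the fixation sequence, each fixation represented by its
  z-scored numeric features concatenated with a learned embedding of its
  AOI code, followed by a scalar regression head on the concatenated final
  states of both directions. The LSTM applies recurrent dropout
  (variational: one mask per sequence per layer and direction, applied to
  the recurrent connection); the GRU variant uses identical hyperparameters
  without recurrent dropout.

The recurrent nets are trained with minibatch Adam on mean-squared error.
The label is z-scored with training statistics and predictions are mapped
back to micrometres; normalizing the target keeps the loss surface
well-scaled at small learning rates. Early stopping monitors the validation
loss and retains the best checkpoint. Variable-length sequences are handled
by masking: padded steps carry the recurrent state through unchanged, so
the "final" forward state is the state at the last valid fixation, and
padding can never influence a prediction. The embedding row for the padding
code is frozen at zero and — by construction of the mask — receives no
gradient.

The default profile follows the reference protocol: up to 5000 epochs,
early-stopping patience 500, Adam at learning rate 1e-4, 50-dimensional
embeddings, and (a package choice, since they are otherwise unspecified) 64
hidden units per direction, batch size 64, recurrent dropout 0.2. The
`"fast"` profile — 200 epochs, patience 25, learning rate 1e-3, 16 hidden
units, 8-dimensional embeddings — is the package's desk-scale training
budget: on the default synthetic benchmark the validation loss reaches its
minimum within the first few dozen epochs (longer training overfits and is
cut by early stopping), so a 60-epoch run already stabilizes the
characteristic model orderings. The benchmark-scale *residual* analyses use
a slightly heavier variant of the fast profile — 32 hidden units, patience
40, and four pooled runs — because the per-subject residual decomposition
is a more delicate quantity than the test RMSE: runs with nearly identical
RMSE can differ in how cleanly they separate the subject baseline from
transient arousal, and pooling residuals over independent splits (as the
repeated-runs protocol prescribes) averages that training variability out.
The implementation is hand-written in RcppArmadillo — forward,
backward and Adam — and its gradients are verified against central finite
differences in the test suite for both cell types, with and without the
embedding channel, on variable-length batches.

## Evaluation protocol

`experiment_rmse()` runs the repeated-split protocol: for each of `l` runs
(default 10), blocks are split at block level into 70% train / 10%
validation / 20% test with a run-specific seed fanned out from the master
seed, the model is trained, and the test RMSE
`sqrt(mean((prediction - truth)^2))` is recorded; the summary is the mean
and SD over runs. Residuals are defined as truth minus prediction
throughout, so per-subject mean truth decomposes exactly into mean
prediction plus mean residual.

Performance analyses operate on test blocks pooled over runs:

* **Group comparison** (`split_by_performance()`): test blocks are split by
  their subject's score relative to the mean score; per-group RMSEs are
  reported per run, and the groups' per-block squared errors are compared
  with a Mann–Whitney U test (U counts strict wins plus half-ties; exact
  enumeration up to 20 pooled observations, otherwise a normal
  approximation with tie and continuity corrections). Using per-block
  squared errors pooled over runs is a package decision — the per-run RMSE
  alternative (10 values per group) is available behind `per_run = TRUE`.
* **Per-subject correlations** (`residuals_by_subject()`, `spearman_rho()`):
  unweighted per-subject means of truth, prediction and *signed* residual
  over test blocks, rank-correlated with scores. Signed residuals are the
  point: the arousal component is dilatory, so under-prediction (positive
  residual) is the engagement-bearing direction.
* **Fisher Z** (`fisher_z_compare()`): the independent-samples formula on
  arctanh-transformed correlations. The two correlations compared here
  share a sample and are technically dependent; the package implements the
  stated independent-samples form and documents the caveat rather than
  silently substituting a dependent-correlations variant.
* **Tertile AUC** (`tertile_groups()`, `roc_auc()`,
  `permutation_auc_pvalue()`): subjects are ranked by score (ties broken by
  subject id); the bottom and top `floor(n/3)` form the classes. AUC is the
  Mann–Whitney probability that a random top-group subject exceeds a random
  bottom-group subject on the measure — identical to the threshold-sweep
  construction, and tested against `U/(n_t n_b)` as an internal identity.
  Significance comes from 10,000 label permutations with the add-one
  estimator `p = (1 + #{AUC* >= AUC}) / (n_perm + 1)`, which cannot return
  zero. No multiple-testing correction is applied; raw significance levels
  are reported.

## The synthetic study generator

The original study's human data are not deposited, so validation rests on a
generator (`synth_config()`, `generate_study()`) whose decomposition is
known exactly. It emulates the study's *shape* — subjects watch three 300-s
videos in one of three presentation modalities; each subject has one
assessment score — and a pupil model with the two drivers the analysis is
designed to separate:

```
pupil(t) = baseline_s − lum_gain · L̃(t) + arousal_gain · A_s(t) + ε(t)
```

* `baseline_s ~ Normal(2100, 300²)` μm per subject.
* `L̃` is the scene luminance — piecewise-constant levels Uniform(0, 1) over
  scenes of Uniform(5, 20) s — low-pass filtered with a 1-s time constant
  (the light reflex is not instantaneous); `lum_gain = 600` μm,
  constrictive.
* `A_s` is a sum of non-negative dilation pulses (unit height, 2-s
  exponential decay) arriving at rate `0.05 · (1 + 4 e_s)` per second,
  where `e_s ~ Beta(2, 2)` is the subject's latent engagement;
  `arousal_gain = 250` μm.
* `ε ~ Normal(0, 60²)` μm measurement noise; diameters are floored at
  300 μm.
* Scores follow `clip(0.15 + 0.7 e_s + Normal(0, 0.07²), 0, 1)`, so
  engagement is the common cause of the arousal pupil component and
  performance.

Fixations tile the timeline (log-normal durations, median 250 ms), saccades
fill the inter-fixation gaps, and blinks arrive as a 0.2/s Poisson process.
Luminance is *not* an input feature anywhere: it reaches the models only
implicitly, through the pupil diameters themselves and through the AOI
schedule — the scene script highlights slide text in bright scenes, images
in dark ones, and the instructor in between — so AOI occupancy carries
luminance information the way real video content does. This is what makes
the headline property non-trivial: a model that learns the
luminance-and-baseline structure well, but cannot anticipate individual
arousal pulses, under-predicts engaged subjects, and the per-subject mean
residual inherits the engagement signal.

What the generator does **not** emulate: photometric realism, main-sequence
saccade dynamics, pupillary hippus, foreshortening artifacts, drift, or any
content-driven gaze semantics. Passing tests on this benchmark demonstrate
that the pipeline recovers a known ground-truth structure of the stated
form — they cannot certify performance on real recordings, where the
luminance-arousal decomposition is neither additive nor stationary.

Default sizes are 60 subjects × 3 × 300 s, about 3600 candidate 15-s
blocks — chosen to exceed the scale of the motivating study while training
in minutes on one CPU. With the stated gains the generated diameter
marginal sits near 1.88 mm (baseline 2.1 mm minus the average luminance
term plus the average arousal term), with the population mean anchored at
the 2.1-mm scale typical of video-viewing pupillometry.

## Numerical choices and degenerate inputs

* Half-open AOI rectangles with priority tie-breaks; points outside all
  regions map to NONE.
* Population (not sample) SD in feature statistics; zero-SD features
  guarded to SD 1, making constant features exactly zero after z-scoring.
* First differences are 0 at the sequence start.
* The LINEAR model uses an SVD pseudo-inverse with tolerance `1e-10`
  relative to the leading singular value.
* Recurrent predictions are floored at machine epsilon to honor the
  positivity contract after inverse normalization (in practice predictions
  sit three orders of magnitude above the floor).
* One master seed fans out to per-run, per-model, per-stream and
  permutation seeds through a small integer hash (`fanout_seed()`); all
  stochastic steps restore the caller's RNG state.
* Degenerate inputs fail loudly: empty training sets, empty validation sets
  for trained models, zero-duration recordings, constant inputs to
  correlation, and non-finite losses all raise errors rather than produce
  silent NaN.

## Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline on the
default 60-subject benchmark with single-run experiments and 80-epoch
fast-profile recurrent training, plus a 6-subject study for structural
tests; statistical kernels are validated against brute-force oracles on
hundreds of small random inputs. These sizes are the package's own choice
of a desk-scale experiment: large enough that the qualitative orderings
(recurrent < input-mean RMSE; diameter features essential; residual more
informative than prediction) are stable across seeds, small enough to run
on a laptop core in minutes.

## Known limitations

* The recurrent implementation is single-threaded and CPU-only by design;
  it is sized for thousands of blocks, not millions.
* Saccade/blink sequences reach the recurrent models only through
  per-fixation covariates, not as independent sequence channels.
* The Fisher Z comparison assumes independent samples (see above).
* Drift correction and fixation-detection algorithms are out of scope: the
  package consumes already-classified events.
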