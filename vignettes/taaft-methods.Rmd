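---
title: "Accumulative fine-tuning for lung-ultrasound classifiers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulative fine-tuning for lung-ultrasound classifiers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the package's scientific model, the design decisions
made where the procedure was genuinely open, and what the synthetic data can
and cannot establish.

## 1. The fine-tuning protocol

The object of study is a binary classifier of lung-ultrasound M-mode images:
class 1 is *absent lung sliding* (the "barcode" pattern suggestive of
pneumothorax), class 0 is sliding and/or lung pulse present. A model
pretrained at one center (M0) is to be adapted to a limited external dataset
drawn from other centers, which serves simultaneously as fine-tuning
substrate and validation data.

One trial with parameter k splits the external data patient-wise into 2k
folds. The training set starts empty and grows by one fold per iteration;
the variable-sized validation set is everything not yet in training, and the
fixed-size validation set is the constant union of the last k folds. At
iteration i (training proportion p = i/2k, i = 1..k) the base model — always
M0, never the previous iteration's model, so the k fine-tuned models are
comparable manipulations of the same starting point — is fine-tuned on the
accumulated folds and evaluated on both validation sets. An experiment runs
n_trials independent trials (different patient-wise splits) and succeeds if
some proportion's trial-wise mean sensitivity and specificity meet
predefined goals on the variable-sized set; the smallest qualifying
proportion is used to fine-tune a final model on a fresh split, followed by
a drift check on the source-domain holdout.

Assumptions worth making explicit:

* *Patients are the exchangeable unit.* All splits (outer folds, inner
  80/20) are patient-wise; a patient's clips never straddle a
  train/validation boundary, including upsampled pool images.
* *Goals are calibrated on the source domain.* The defaults (sensitivity
  0.901, specificity 0.793) represent the lower bound of the pretraining
  cross-validation interval: the external data should be handled at least
  as well as the local data were.
* *"Meets the goal" is inclusive* (>= rather than >), so exact ties do not
  flip the success verdict.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 3 | number of training-set increments; 2k folds |
| `n_trials` | 5 | independent patient-wise splits averaged |
| goals | 0.901 / 0.793 | minimum mean sensitivity / specificity, variable-sized set |
| `target_positive_fraction` | 0.26 | class distribution restored by pool upsampling (fraction of positives typical of a dedicated single-center training set) |
| inner fraction | 0.8 | fit share of the inner train/secondary-validation split |
| `threshold` | 0.5 | operating point for the confusion matrix |

The upsampling count is `ceil(f·N_neg/(1−f)) − N_pos`: the smallest number
of added positives that brings the positive fraction to at least `f`. Draws
are without replacement until the eligible pool (pool images whose source
clip is in the fit set) is exhausted, then with replacement.

## 2. M-mode preprocessing

Clips are segmented into consecutive, non-overlapping 3-s windows
(`floor(fps·3)` frames; a shorter remainder is dropped). The pleural line is
located heuristically on the first frame: the row maximizing the row-wise
mean intensity over the lower 80% of the frame (the near field is excluded
because subcutaneous tissue can be bright), extended ±2 rows. A detector
trained for this task can replace the heuristic by supplying an explicit ROI
per clip.

Columns are scored by the **sum of intensities within the ROI row band of
the first frame**. The field's convention ("brightest column") does not pin
down a statistic; the band sum was chosen because a single-pixel maximum is
speckle-fragile, and an all-frame average would leak temporal information
into a purely anatomical choice. Ties break to the lower column index so the
candidate set is deterministic. The 10 highest-scoring distinct columns of
each absent-sliding clip become candidate M-modes — the top one is the main
example, the other 9 are sequestered into the upsampling pool. Negative
clips contribute only their main M-mode by default (`pool_negatives`
enables pooling for them too). M-modes are reconstructed exactly (pixel
(r, t) = frame t, row r, chosen column) and resized to 224×224 with
bilinear interpolation.

All coordinates in this package are 1-based with inclusive intervals, the
native indexing of R.

## 3. The baseline classifier and its features

The pluggable classifier contract is three functions (`fit`, `fine_tune`,
`predict_scores`) plus serializability; deep networks can register against
it. The built-in baseline is a weighted logistic model trained by
deterministic full-batch gradient descent (no stochastic minibatching, zero
initialization, fixed iteration count), with inverse-frequency class weights
by default and a small L2 penalty (1e-3). Fine-tuning warm-starts from the
base state's coefficients *and its feature standardization* — domain shift
must remain visible to the optimizer rather than being re-standardized away
— with the step size scaled by 0.1 over 600 iterations, chosen so that
fine-tuning converges stably on fold-sized training sets; `fine_tune_iter
= 0` reproduces the base model exactly, which the tests use as a warm-start
identity check.

Features per M-mode image: the image is min-max normalized (gain
invariance), the pleural band is located as the brightest row, and the
per-row temporal standard deviation profile of the sub-pleural region is
averaged into 16 pleura-anchored bins; these are complemented by the mean
supra-pleural row-sd, the mean absolute column-to-column change, and global
intensity statistics. Anchoring the profile to the detected pleura rather
than to absolute depth removes the variance caused by pleura position
differing across clips, which otherwise destabilizes fine-tuning when a
fold contains only a handful of distinct positive clips.

Metrics: sensitivity, specificity and accuracy at the fixed 0.5 threshold
(the protocol compares models at a single operating point); AUC by the
mid-rank concordance estimator, ties counted 1/2 — algebraically identical
to the trapezoidal ROC area on finite samples. Metrics whose denominator
class is absent are reported as `NA`, never as 0.

## 4. The synthetic generator

`generate_clip()` builds grayscale B-mode stacks with a bright pleural band
(lateral brightness modulated by a smooth bump so the brightest-column
choice is well defined), static speckle above the band, and sub-pleural
speckle that decorrelates frame to frame — lateral drift of one pixel per
frame plus partial resampling with autocorrelation 0.9 — when sliding is
present, but is frozen up to additive noise when absent. Institution
profiles control gain, noise, pleural depth range, metadata sampling
weights, and `sliding_scale`, the fraction of sub-pleural texture energy
that actually decorrelates.

The default study conditions mirror a pooled multicenter cohort: 60
patients, 2–4 clips each, 13% positive clips (the imbalance typical of
external LUS data, versus 26% for the dedicated local cohort), 30 fps, 3-s
clips, three external centers with heterogeneous vendor/preset/location
mixes, one of which contributes a small share of linear-probe clips so the
default manifest filter has work to do. Frames default to 64×64: large
enough for a realistic pleura/sub-pleura geometry, small enough that a full
experiment runs in seconds.

`sliding_scale` (0.60/0.70/0.50 externally, 1.0 locally) is the lever that
produces the domain shift: external sliding is attenuated relative to the
local domain, so a locally calibrated decision boundary misreads a fraction
of external sliding clips as absent — degraded baseline specificity with
intact sensitivity — while the external classes remain separable so
fine-tuning can recover. These values were fixed once so that the baseline
external specificity lands well below the in-domain level while within-
external class margins stay wide; they are study conditions, not fitting
knobs. An optional probe-motion jitter (`jitter_prob`, off by default) adds
global lateral motion to absent-sliding clips, creating the
false-negative-like hard cases operator movement produces in practice.

What the generator does *not* emulate: physical ultrasound formation (no
ray tracing or RF modeling), anatomical structure beyond the pleural band,
rib shadows, A-/B-lines, lung point (partial sliding), mislabeled clips, or
probe-dependent beam geometry. Passing tests on this data therefore
establishes the *protocol machinery* — splits, schedules, upsampling
hygiene, goal assessment, metric arithmetic, audit statistics — and the
qualitative premise that fine-tuning recovers shift-degraded specificity;
it does not certify performance on real LUS data or for any particular
architecture.

## 5. Subgroup audit

For each metadata field (vendor, probe, preset, depth binned at the
conventional <6 / 6–20 / >20 cm cut points, left-closed; institution) and
each ground-truth stratum (positives probe sensitivity effects, negatives
specificity effects), the audit runs a Pearson chi-squared test of
correctness-vs-level independence (no continuity correction) and a
classical one-way ANOVA of the prediction error against level. "Error" is
defined as |score − label|, the simplest continuous residual for a
probabilistic binary prediction. Significance is inclusive at p <= 0.05 and
p-values are reported raw — no multiple-testing correction — so the report
carries an explicit note to that effect. "Unavailable" metadata is kept as
its own level when it has at least 5 examples in the stratum and dropped
otherwise; levels with zero examples are dropped with a warning, and a
stratum in which one correctness outcome is entirely absent yields the
degenerate chi-squared of 0 (nothing to test).

The fragility index of a significant field is computed per level: the
minimum number of correctness flips among that level's examples rendering
the field's chi-squared p > alpha. Because the statistic depends on the
level only through its correct/incorrect counts, the exact minimum is found
by scanning reachable count compositions in increasing flip cost — m flips
move the level's correct count by at most m — equivalent to exhaustive
search at any level size; the tests verify it against a brute-force flip
enumeration. A level that cannot overturn the result by flipping all of its
examples gets `NA`.

## 6. Numerical and degenerate-input choices

* Greedy fold assignment places each shuffled patient into the currently
  smallest fold **by clip count** (patient-count balancing was the
  alternative; clip counts are what validation set sizes are made of), ties
  to the lowest fold index.
* Fold order is accumulation order; all randomness lives in the patient
  shuffle. Trial seeds derive from the master seed as `seed + 1000·t`;
  per-iteration inner-split and upsampling seeds derive from the trial seed
  by fixed offsets. Fresh inner 80/20 splits are drawn at every iteration
  rather than reused — each iteration is an independent fine-tuning
  exercise.
* If an inner 80/20 draw strands every positive patient in the secondary
  set, the split is redrawn deterministically (up to 50 derived seeds); only
  a training fold *union* genuinely missing a class aborts the trial, which
  the experiment records as incomplete while preserving finished trials.
* The pleura locator breaks ties toward the shallowest qualifying row; a
  clip shorter than one segment yields no records; an all-zero frame scores
  all columns 0 and column 1 wins.
* Labels accept the aliases "absent"/"present" on CSV read and are stored
  as 1/0. Depth bins are presentation-time, never storage.
* Statistical wrappers delegate to `stats::chisq.test(correct = FALSE)` and
  the classical F computation; closed forms appear only in tests as
  oracles.

## 7. Problem sizes

The test suite exercises the full pipeline at deliberately small scale:
unit fixtures use 6–24 patients with 48×48 frames at 10 fps, and the
end-to-end suite uses a 40-patient local cohort plus the default 60-patient
external cohort at full 64×64/30 fps resolution, sizes at which a complete
5-trial experiment (including clip synthesis and preprocessing) finishes in
well under a minute. `scripts/acceptance.R` uses the same sizes. Users
studying fold-size effects or rarer imbalances should scale `n_patients`
up; all operations are linear in clip count except the audit's exhaustive
oracles, which are only used in tests.

## 8. Known limitations

* The baseline classifier is a linear model on engineered features; it is
  the protocol's reference implementation and plug-in example, not a
  substitute for a CNN on real data.
* Trial aborts are possible by construction when a 13%-positive, 60-patient
  dataset is cut into 6 patient-wise folds (a fold can, rarely, contain no
  positive patient). The experiment reports itself incomplete rather than
  silently resplitting, since resplitting would bias fold statistics.
* Saliency mapping and qualitative error review of the original workflow
  require deep-network internals and clinician eyes respectively; both are
  out of scope.
* The fragility index's exact construction is not standardized in the
  field; the definition above is documented and oracle-tested rather than
  claimed to match any particular prior implementation.
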