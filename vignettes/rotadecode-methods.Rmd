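---
title: "Models and methods behind rotadecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rotadecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices the package
makes: the design generator, the synthetic signal model, the decoding and
RSA machinery, the Bayes-factor construction, and what the simulations can
and cannot say about real EEG.

## 1. The experimental design and its generator

The design emulated is a rapid serial visual presentation (RSVP) study: 60
objects in 8 in-plane rotations (0°–315° in 45° steps), 15 repetitions per
object × rotation × rate, at two presentation rates (5 Hz and 20 Hz; 33 ms
stimulus duration, hence 167 ms and 17 ms inter-stimulus intervals). Stimuli
are organized in 120 sequences of 120 presentations; each sequence shows
every object exactly twice, in two different rotations, with all
(object, rotation) pairs unique within a sequence, and each run of 4
consecutive same-rate sequences covers the full object × rotation grid
exactly once. Fixation-bullseye targets (2–4 per sequence, ≥ 10
presentations apart, never in the first or last 10 positions) engage the
participant; they replace the fixation symbol, not the stimulus, so target
presentations keep their object labels.

`generate_design()` builds this by direct construction rather than
rejection sampling: within each block of `n_rotations / 2` same-rate
sequences, each object's rotations are shuffled once and split into
disjoint pairs, one pair per sequence. Every sequence then automatically
contains the object twice in two different rotations, and the block covers
the grid exactly once — the constraints hold by construction, which is both
faster and easier to verify than resampling. Presentation order within a
sequence, the pairing of rotations (the design leaves it unconstrained, and
we treat it as free), the block order over rates, and target placement are
the only random choices, all driven by one seed. Target positions are drawn
uniformly among gap-respecting configurations via the standard bijection
(subtract the forced gaps, sample without replacement, add them back).
Onsets are placed on an integer-millisecond grid at `round(1000 / rate)`
spacing; no display-refresh model is simulated, since nothing downstream
consumes sub-millisecond timing.

`validate_design()` re-checks every constraint independently of the
generator and reports violations as data instead of raising, so it can
audit externally supplied tables.

## 2. The synthetic epoch model

`generate_subject()` turns every presentation into one epoch of −100 to
800 ms at 250 Hz (the full-size profile; tests use shorter windows). The
signal model is a sum of components, each

```
signal(trial, channel, t) = amplitude × gain_subject × gain_rate ×
                            envelope(t) × pattern(labels)[channel]
```

* **Patterns** are fixed unit-norm Gaussian channel vectors keyed by the
  trial's labels: one per (object, rotation) for the `rotation_specific`
  component, one per object (shared across its rotations) for
  `rotation_tolerant`, one per category for `category_level`. Unit norm
  makes `amplitude` interpretable as the peak multivariate signal norm in
  units of per-channel noise SD.
* **Envelopes** are Gaussian bumps (SD `width_ms`, default 30 ms) truncated
  to post-stimulus time, or box-cars for sustained codes. Defaults place the
  rotation-specific peak at 116 ms and the rotation-tolerant peak at
  192 ms — the two-stage structure the analyses are designed to resolve.
* **Rate attenuation** multiplies the amplitude for every rate above the
  slowest in the design (default 0.5), emulating weaker object signals
  under fast presentation.
* **Subject gain** is drawn once per component per subject from
  Normal(1, `subject_sd` = 0.2), floored at 0.
* **Noise** is zero-mean Gaussian with compound-symmetric spatial
  correlation across channels (default 0.3), AR(1) temporal correlation
  (lag-1 coefficient 0.7) and unit marginal variance scaled by `noise_sd`.
  The AR(1) choice is a cheap, plausible stand-in — the real noise spectrum
  of EEG is not characterized here, and this is flagged as such.

The default component amplitude of 2.5 was chosen once as a realistic
regime: with 32 channels it yields clearly above-chance but far-from-ceiling
60-way decoding, so peak latencies are recoverable without saturating the
accuracy curve. Electrode positions are a Fibonacci lattice on the unit
sphere — the searchlight only needs geometry, not a named montage.

Pre-stimulus samples carry noise only. Epochs are generated independently:
overlapping responses from neighbouring RSVP items are *not* simulated.
That keeps the ground truth clean but means the simulations cannot probe
artifacts of temporally overlapping responses (or eye/muscle artifacts,
filtering distortions, or channel interpolation) that real recordings
contain. Passing tests therefore validate the *analysis machinery*, not
robustness to real-world preprocessing.

Reproducibility: a subject's data is a pure function of
`(seed, subject_index)`; the generators set the RNG state locally (via
`withr::with_seed`) and restore the caller's state, with all inputs forced
before seeding, so results do not depend on call context or evaluation
order.

## 3. Decoding

Features are single-time-point channel vectors (no temporal windows).
The classifier is multiclass LDA with equal priors and a shrinkage
covariance `S = (1 − λ) Σ̂ + λ (tr Σ̂ / p) I`. The study this design
emulates does not state its regularization, so λ is exposed with default
0.01 (standard regularized-LDA practice); results should be reported with
λ. Ties in discriminant scores resolve to the lowest class index,
deterministically. At `λ = 1` the rule degenerates to nearest centroid; at
`λ = 0` it is classical LDA and inherits its affine invariance (verified by
test).

The two cross-validation schemes share folds indexed by (test rotation ×
left-out repetition): the test set is always the left-out repetition of
every object at the test rotation, identical across schemes, and training
budgets are matched at `n_reps − 1` trials per object. The tolerant
scheme's training repetitions per non-test rotation are chosen by the
deterministic rule `left_out_rep + 1, left_out_rep + 2, …` (cyclic); the
subsampling is not specified by the emulated design, and determinism beats
silent randomness — a seeded random option exists. A matched budget
requires `(n_reps − 1)` divisible by `(n_rotations − 1)`; infeasible
configurations error rather than silently unbalancing.

The channel searchlight takes, for each channel, the channel plus its 4
nearest neighbours (Euclidean distance on electrode coordinates; ties
broken by channel index with a warning) and stores the neighbourhood's
decoding accuracy at the centre channel.

## 4. RSA

The neural RDM is cross-validated pairwise decoding accuracy: entry (i, j)
at each time-point is the leave-one-repetition-out 2-class LDA accuracy for
conditions i and j (0.5 = indistinguishable, 1 = fully distinct). Each
unordered pair is computed once (the fold-averaging order is therefore
symmetric by construction); the diagonal is stored as 0 and excluded from
all correlations. The implementation uses per-condition sufficient
statistics (channel sums and Gram matrices per time-point) with rank-1
leave-one-out downdates, which is algebraically identical to refitting and
an order of magnitude faster; a test pins it against a naive refit oracle.
Identical, noise-free trial sets make the within-pair covariance zero, and
this degenerate input errors explicitly.

The rotation-tolerant model RDM predicts dissimilarity 0 for same-object
pairs (any rotations) and 1 otherwise. Control models are cosine-distance
RDMs over condition feature vectors. Since bundling a trained
convolutional network is out of scope, `standin_features()` provides a
deterministic synthetic substitute labelled as such: each object is a
seeded mixture of Gaussian blobs in a small image, rotations rotate the
blob constellation analytically, and three pseudo-layers apply increasing
average pooling (1×1, 2×2, 4×4) to the rectified image. This reproduces
the two properties the controls exist for — strong rotation sensitivity
and graded similarity across layers — without claiming to model any real
network; externally computed feature tables can be supplied instead.

The partial correlation rank-transforms the strict lower triangles
(Spearman-style) before residualizing neural and model vectors on the
controls plus an intercept and correlating the residuals. Rank-based is the
default because decoding-based dissimilarities are only monotonically, not
linearly, related to underlying discriminability; invariance to monotone
transforms is tested. Pearson is available via `method = "pearson"`.
Constant vectors after ranking return `NA` with a warning rather than a
spurious coefficient.

## 5. Temporal generalization

`tg_within()` uses exactly the folds of `decode_timecourse()`, training at
every time-point and testing at every other; the diagonal equals the
decoding time-course to machine precision by construction (asserted in
tests). `tg_cross_rate()` trains on one rate and tests on the other, in
both directions, then averages the slow→fast matrix with the transpose of
the fast→slow matrix. Rows are fixed as slow-rate (5 Hz) time and columns
as fast-rate (20 Hz) time. (The emulated study describes the transposition
once as applied to the train-fast matrix and once to the train-slow matrix;
the two statements conflict, so the package fixes the axis convention above
and documents the choice rather than resolving the discrepancy.) Cross-rate
training uses all repetitions of the training rate with one fold per test
rotation: train and test sets come from different rate conditions and are
disjoint by construction, so leave-one-out would only discard data.

## 6. Group statistics

The Bayes factor integrates the noncentral-t likelihood over the notched
Cauchy prior by adaptive quadrature (`stats::integrate`, relative tolerance
1e-8; the absolute tolerance is scaled to the null likelihood so that a
negligible opposite tail cannot trigger spurious roundoff failures while
each tail still contributes to BF10 at the requested relative accuracy).
The prior's renormalization constant is closed-form,
`Z = 1 − (2/π) atan(notch / width)`, identical for the one- and two-tailed
variants. A 10⁶-draw Monte-Carlo importance oracle over the truncated
Cauchy pins the quadrature to within 2% across a grid of t and n in the
acceptance suite. Accuracies are tested on the proportion scale (no
variance-stabilizing transform), there is no correction across time-points
(Bayes factors are reported per time-point), and evidence is classified at
the conventional display thresholds 10 and 1/10. Zero variance across
subjects (e.g. testing a condition against itself) is an error, not a
silent infinity.

Onset latency is the first post-stimulus time-point with BF10 > 10 — a
single-point crossing, with no consecutive-points requirement, which is the
simplest defensible reading; peak latency is the argmax of the group-mean
statistic in the post-stimulus window.

Confidence bands are percentile bootstraps over subject resampling. The
percentile bootstrap is first-order accurate, and the calibration test
documents the expected modest undercoverage at small cohort sizes
(≈ 92% at n = 25 for a nominal 95% band).

## 7. Problem sizes and test design

The test suite runs the full 60 × 8 × 15 design where the quantity under
test depends on it (the chance-recovery check, design constants, the 480 ×
480 RDM dimension) and a scaled profile everywhere else: 12 objects × 4
rotations × 7 repetitions, 16 channels, epochs to 300–400 ms. The scaled
profile preserves the matched-budget arithmetic (6 training trials per
object = 2 per non-test rotation) and the 250 Hz sampling grid, so latency
recovery within ±2 samples means the same thing at both scales.

One statistical subtlety is worth recording: the grand-mean accuracy of a
signal-free subject averages 36,000 test classifications, but they share
noise realizations and classifiers across folds and time-points, so its
sampling spread is larger than the naive binomial bound. The chance
recovery test therefore replicates over independent simulated subjects and
t-tests the replicate means against 1/60, which uses genuinely independent
units.

Parameter-recovery checks are run at the cohort level (group-mean
time-courses), matching how the latencies are interpreted scientifically;
single subjects at the default SNR carry ±1–2 samples of peak jitter.

## 8. Known limitations

* Epochs are independent; RSVP response overlap, periodic steady-state
  components, and multiplexed representations of successive items are not
  simulated.
* The noise model (compound-symmetric spatial + AR(1) temporal) is a
  stand-in; no 1/f spectrum, no artifacts, no channel heterogeneity.
* The control-model features are synthetic stand-ins with the right
  invariance structure, not a trained network's activations.
* The raw-EEG preprocessing chain (filtering, bad-channel interpolation,
  re-referencing) is out of scope: data enter at the epoch level.
* Searchlight output is descriptive per subject; no group-level statistical
  maps are produced.
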