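# rotadecode

Time-resolved multivariate decoding of object identity from EEG under
in-plane image rotation, as a fully simulatable, testable R pipeline.

## The problem

When an object is shown rotated in the picture plane, early visual responses
are tied to the specific image (orientation and all), while later responses
are thought to carry an *abstract*, rotation-tolerant representation of the
object. Time-resolved EEG decoding can separate the two with a pair of
cross-validation schemes over a design in which every object appears at
several rotations:

* **Fixed-rotation decoding** — train and test a 60-way classifier on the
  *same* rotation. Any information, low-level or abstract, contributes.
* **Rotation-tolerant decoding** — train on 7 rotations, test on the held
  out 8th, with the training budget matched (always `n_reps − 1 = 14`
  training trials per object) and the *identical* test trials in both
  schemes, so the two accuracies are directly comparable.

`rotadecode` implements that full analysis — and a synthetic-data generator
that emulates the experiment's design and hypothesized signal structure, so
every stage can be validated against a known ground truth without any
recordings. It targets researchers in cognitive neuroscience who want a
reference implementation of these analyses, or a ground-truthed sandbox for
method variants.

## What is inside

| Stage | Functions |
| --- | --- |
| Experiment design (RSVP sequences, counterbalancing, targets) | `design_config()`, `generate_design()`, `validate_design()`, `stimulus_timing()` |
| Synthetic multi-subject epochs with injected signal components | `synth_config()`, `signal_component()`, `generate_subject()`, `generate_cohort()` |
| Shrinkage-LDA decoding, CV schemes, channel searchlight | `fit_lda()`, `build_scheme()`, `decode_timecourse()`, `searchlight_timecourse()` |
| RSA: pairwise-decoding RDMs, model RDMs, partial correlation | `neural_rdm()`, `rotation_tolerant_model()`, `feature_model_rdm()`, `standin_features()`, `partial_corr_timecourse()` |
| Temporal generalization, within and across presentation rates | `tg_within()`, `tg_cross_rate()` |
| Group statistics: notched-Cauchy Bayes factors, bootstrap bands, latencies | `notched_prior()`, `notched_bf()`, `bf_timecourse()`, `difference_bf_timecourse()`, `bootstrap_ci()`, `latency_summary()` |
| Orchestration | `pipeline_config()`, `run_pipeline()` |

The decoder is multiclass LDA with equal priors: a test sample `x` is
assigned to the class whose mean `m_k` maximizes
`x' S⁻¹ m_k − m_k' S⁻¹ m_k / 2`, where the pooled within-class covariance is
shrunk towards a scaled identity, `S = (1 − λ) Σ̂ + λ (tr Σ̂ / p) I`
(default `λ = 0.01`).

The group-level test is a Bayesian t-test with a point null and a *notched*
Cauchy prior on the standardized effect `d`: a Cauchy(0, r = 0.707) prior
with the interval `|d| < 0.5` excluded and the remaining mass renormalized
(one-tailed for directional tests, two-tailed for difference tests):

```
BF10 = ∫ f_nct(t; ν, d√n) π(d) dd  /  f_nct(t; ν, 0)
```

with `f_nct` the noncentral-t density, so `BF10 > 10` is strong evidence for
a substantial (`d > 0.5`) effect, and `BF10 < 1/10` favours the null.

## A worked example

A desk-scale version of the study — 12 objects × 4 rotations × 7
repetitions at 5 and 20 Hz, 4 simulated subjects — with the default
two-component signal (rotation-specific peaking at 116 ms, rotation-tolerant
at 192 ms):

```r
library(rotadecode)

cfg <- design_config(n_objects = 12, n_rotations = 4, n_reps = 7,
                     rates = c(5, 20), seq_length = 24,
                     targets_per_seq = c(1L, 2L), min_target_gap = 3L,
                     edge_exclusion = 2L, seed = 1)
design <- generate_design(cfg)
validate_design(design, cfg)      # 0 rows: all constraints hold

synth <- synth_config(n_subjects = 4, n_channels = 16,
                      epoch_window_ms = c(-100, 300), seed = 2)
cohort <- generate_cohort(design, synth)
cohort[[1]]
#> <epoch_set S01: 672 trials x 16 channels x 101 time-points (-100..300 ms)>

acc <- function(scheme) t(sapply(cohort, function(ep)
  decode_timecourse(filter_epochs(ep, rate_hz = 5), scheme)$accuracy))
acc_fixed <- acc("fixed_rotation")
acc_tol   <- acc("rotation_tolerant")
times <- seq(-100, 300, by = 4)

times[which.max(colMeans(acc_fixed))]   # group fixed-rotation peak: 120 ms
times[which.max(colMeans(acc_tol))]     # group rotation-tolerant peak: 192 ms

bf <- bf_timecourse(acc_tol, null_value = 1 / 12, times_ms = times)
latency_summary(bf, colMeans(acc_tol))
#> # A tibble: 1 × 2
#>   onset_ms peak_ms
#>      <dbl>   <dbl>
#> 1      124     192
```

The group fixed-rotation time-course peaks early (120 ms, driven by the
rotation-specific component) while rotation-tolerant decoding peaks late
(192 ms, at the injected tolerant latency); the notched Bayes factors put
the onset of strong evidence at 124 ms. `autoplot()` methods exist for
every result type, and `run_pipeline()` executes all stages end to end,
writing tidy TSV tables plus a JSON run manifest.

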