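---
title: "Decoding EEG brain age and testing the state vs. trait hypotheses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding EEG brain age and testing the state vs. trait hypotheses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A decoder trained to predict chronological age (CA) from the EEG of healthy
subjects produces, for any new recording, a *brain age* (BA). The difference
BA − CA — the brain-age gap — has been proposed as a pathology biomarker.
Two competing readings of the gap exist. Under the **state hypothesis** the
gap tracks current brain state and should change when a subject acquires or
recovers from EEG pathology. Under the **trait hypothesis** the gap is a
stable individual characteristic, unaffected by such transitions. The two
readings make different predictions for subjects with repeated clinical EEG
sessions, and in particular for subjects whose pathology label flips
between sessions.

This package implements the full analysis chain needed to pose that
question — preprocessing, a temporal convolutional age regressor trained by
cropped decoding, quadratic bias correction, a two-threshold gap biomarker,
longitudinal change-rate and moment-of-transition statistics, permutation
tests, and amplitude-gradient saliency maps — together with a synthetic
clinical-EEG cohort generator that plants known trait and state components,
so that every stage of the analysis is testable end to end without access
to any gated corpus.

## The synthetic world

`generate_cohort()` draws subjects with:

* a chronological age at first session uniform on `age_range`
  (default 18–86 years);
* a number of sessions from a shifted Poisson
  (`recordings_per_subject_mean`, default 2.5; transition subjects are
  guaranteed at least two) and lognormal inter-session intervals
  (`interval_months_mean`, default 12 months, sigma 0.5 on the log scale) —
  the skewed counts and month-scale gaps typical of clinical archives;
* a pathology biography: persistent non-pathological, persistent
  pathological (`pathology_fraction`), or a single label flip at a random
  session boundary with direction split 50/50 (`transition_fraction`);
* a per-subject **trait offset** drawn once from N(0, `trait_sd`²) and a
  **state effect** (`state_effect` years) added while the label is
  pathological. The *effective age* that drives signal synthesis is
  CA + trait + state.

`simulate_recording()` renders the effective age into signal: pink
(1/f) background noise (10 µV per channel) plus an alpha rhythm whose peak
frequency declines linearly with effective age,

  f_peak = 11.0 − 0.03 · effective_age (Hz),

with amplitude 20 µV weighted toward occipital electrodes, a slow
waxing-and-waning envelope, and a random phase. Pathological recordings
receive 50% more delta/theta (0.5–8 Hz) power and 30% less alpha amplitude
— the classic slowing-plus-alpha-attenuation picture of abnormal clinical
EEG. All coefficients live in `cohort_config()` and the generator is
bit-reproducible for a fixed seed.

Two deliberate features deserve emphasis.

**Session variability.** Repeated sessions of a real subject do not have
identical spectra. The generator therefore jitters the alpha peak per
session (`alpha_session_jitter_hz`, default 0.1 Hz, the conservative end of
reported individual-alpha-frequency test–retest variability; 0.1 Hz
corresponds to ≈ 3.3 years of apparent age). Without this term any
deterministic decoder reproduces its prediction exactly on a subject's
spectrally identical sessions, split-half gap consistency is ≈ 1 even with
`trait_sd = 0`, and the state-vs-trait contrast is degenerate by
construction. This was measured, not assumed: with jitter disabled, the
within-subject decoding-error ANOVA gives a between-subject mean square
two orders of magnitude above the within-subject one.

**What the generator does not emulate.** Artifacts, sleep, epileptiform
discharges, inter-channel noise correlation, realistic report language, and
the file/session layout of real clinical archives are all out of scope. A green test therefore
establishes that the *analysis machinery* recovers planted structure of
realistic magnitude — not that the decoder would reach any particular
accuracy on real clinical EEG.

## Preprocessing

`preprocess_recording()` applies, in this order: channel selection and
reordering to a fixed 10-20 montage (clinical label dialects such as
`EEG FP1-REF`/`-LE` are normalized), amplitude clipping at ±800 µV, common
average referencing, resampling to 100 Hz, and removal of the first minute
(default; the head of a clinical recording carries most technical
outliers). Clipping precedes re-referencing, following the order the
procedure is conventionally stated in. Resampling is FFT-based band-limited
resampling — deterministic, exact at equal rates — rather than a polyphase
filter; no installed package provides a polyphase resampler and the two are
interchangeable for band-limited EEG at these rates. Recordings shorter
than `min_duration_s` after the chain are excluded. The 15-minute minimum
used for longitudinal derivative construction and the 2-minute selection
minimum are two values of the same `min_duration_s` knob.

Channel-wise standardization statistics (mean, SD pooled over training
recordings) and the min–max age scaling are fit on the training split only
and carry a provenance tag (`split_tag`, `fit_on`) so leakage is auditable.
Ages outside the training range are clamped to [0, 1] with a warning at
scale time; predictions are never clamped after unscaling.

## The age regressor

The decoder is a temporal convolutional network: `n_blocks` residual blocks
(two dilated valid-mode convolutions per block, ReLU, dilation doubling per
block), a per-timestep linear head and a sigmoid output in [0, 1] that is
unscaled to years via the training-age min–max. The desk-scale default —
3 blocks, kernel 5, 32 filters, receptive field 57 samples (0.57 s at
100 Hz) — is deliberately small; the architecture family, not the exact
width, is what the analysis depends on, and every hyperparameter is
overridable in `model_config()`.

Since no autodiff framework is available in this environment, the forward
and backward passes, AdamW, and cosine learning-rate annealing are
implemented directly (`R/tcn.R`). The backward pass doubles as the input
gradient needed for saliency analysis, and both are verified against
central finite differences in the test suite.

Training uses *cropped decoding*: maximally overlapping
receptive-field-length windows at one-sample stride. Materializing every
crop is wasteful, so training samples `crops_per_recording` random crops
per recording per epoch, while prediction runs the network convolutionally
over the full recording — which yields exactly the per-crop sigmoid outputs
of all one-sample-stride crops (equality with materialized crops is
asserted in the tests to machine precision). The per-recording brain age is
the arithmetic mean of per-crop outputs (the standard aggregation choice;
the source protocol does not specify one). Channel-dropout augmentation
zeroes each input channel of a training crop independently with probability
`channel_dropout_p` (default 0.2), training time only, without rescaling.
The loss is L1 on scaled targets; defaults follow the reference protocol
(35 epochs, batch 128, AdamW, cosine annealing), with smaller
epoch/crop budgets used in tests purely for runtime.

Determinism: "same seed, same model" holds up to floating-point reduction
order; tests compare losses exactly on this platform but predictions with
tolerances.

A practical robustness note: from a random initialization the network
spends its first 100–200 optimizer steps near the predict-the-median
constant before the frequency-selective filters break symmetry, and the
escape step varies considerably with the seed. Budgets in the analysis
scripts are therefore sized at roughly twice the typical escape time;
training runs that look flat at a loss of ~0.2 (scaled units) for a third
of the schedule are the signature of this plateau, not of a broken input
pipeline.

## Evaluation protocol

`run_cv()` shuffles *subjects* (never recordings) with a fixed seed into k
folds; each fold's model trains on the non-pathological recordings of the
other folds and predicts every recording of the held-out subjects, so each
recording is an out-of-sample validation prediction exactly once and
pathological recordings are inference-only. `run_final_evaluation()` trains
`n_runs` models with varying seeds on all training subjects and averages
their predictions on a disjoint evaluation split, retaining per-run models
for saliency analysis. Subject overlap between splits is a hard error.

## Bias correction and the gap

Age decoders regress toward the training mean, so the raw gap is negatively
correlated with CA. Following the source protocol, a quadratic
`gap ≈ a·CA² + b·CA + c` is fit to the *pooled CV validation predictions of
non-pathological recordings* and then frozen: every later gap — final
evaluation, pathological recordings, longitudinal cohorts — is corrected by
subtracting the model. On its own fit set the correction is an orthogonal
projection (mean-zero residuals, refit coefficients ≈ 0, idempotent), which
the tests assert. Subjects with several recordings enter group comparisons
through their per-subject mean corrected gap.

Both R² conventions are available: the standard 1 − SSres/SStot (default)
and the explained-variance ratio SSreg/SStot that the source text prints;
they coincide for least-squares-calibrated predictors.

## Biomarker and longitudinal statistics

The pathology biomarker is a two-threshold rule: gaps inside the closed
interval [lo, hi] are non-pathological. `optimize_thresholds()` searches
midpoints of consecutive sorted unique gaps plus ±Inf — sufficient for any
interval rule — maximizing balanced accuracy, with a deterministic
tie-break (widest non-pathological interval, then smallest lo). Boundary
gaps classify as non-pathological, per the "within these thresholds"
convention. The achieved BACC is a rank statistic: invariant under strictly
monotone transforms of the gaps. A single age cut (`age_threshold_proxy()`)
provides the baseline the biomarker must beat. Thresholds are fit per CV
fold and carried to final evaluation (`fold_pairs`), with a pooled variant
used for cohort-level analyses.

`change_rates()` computes, per subject and pathology status, the slope of
the corrected gap over time (same-day recordings averaged first; time in
365.25-day years), then averages pair slopes per subject.
`transition_rate()` instead evaluates the single consecutive pair that
spans the label flip of a TNPP/TPNP subject. A flip pair sharing a date is
a hard error rather than an infinite rate.

## Statistical tests

Permutation machinery is implemented here because it is the analysis's
constructed null: group-membership shuffles for mean-gap differences
(two-sided), label shuffles against a *fixed* threshold pair for the
biomarker BACC (one-sided, greater — "better than chance" is directional).
P-values use add-one smoothing, (1 + #extreme)/(n + 1), so the floor at
100,000 samples is 1e-5 — the resolution of the smallest p the source
reports. The classical tests delegate to `stats::` where possible (paired
t, Kolmogorov–Smirnov, Wilcoxon–Mann–Whitney); Brunner–Munzel is
implemented from the published statistic and Satterthwaite degrees of
freedom, with values cross-checked against an independent implementation.
Sidedness is not stated in the source anywhere; all classical tests are
two-sided here and the choice is recorded in each result object.

One calibration subtlety: the BACC permutation null is *discrete*, and ties
between permuted and observed statistics count as extreme, so its p-values
are valid but conservative (sub-uniform). The test suite asserts validity
(type-I rate ≤ α) for it, and the 3–7% two-sided calibration band only for
the continuous-statistic tests.

## Trait consistency

To quantify trait structure the pipeline correlates, across subjects, the
corrected gap of the first session with the mean corrected gap of the
remaining sessions (one-sided: only positive correlation evidences a
trait). Because CA is nearly constant within a subject, *any* residual
decoder miscalibration beyond the quadratic correction is shared between
the two halves and would masquerade as a trait; both halves are therefore
deconfounded by partialling out a cubic polynomial of their own mean CA
before correlating. Run-averaged predictions (final-evaluation ensembles)
further shrink the subject-stable component of decoder error; the
transfer-study design below relies on this.

## The in-silico state/trait experiment

The acceptance experiment builds two worlds, both with pathology occurring
only through single label transitions, analyzed in a transfer design
(ensemble trained and bias-calibrated on a separate non-pathological
cohort, then applied to the longitudinal cohort — matching the design in
which longitudinal datasets are predicted by the final-evaluation models):

* **trait world** — `trait_sd = 6`, `state_effect = 0`, and pathology as a
  *label without spectral consequence* (`pathology_lowband_gain = 1`,
  `pathology_alpha_gain = 1`). This is deliberate: a zero state component
  means pathology does not move the features the decoder reads. If the
  pathology signature (slowing, alpha attenuation) were kept, any spectral
  decoder would transduce it into a label-linked decoded-age shift — a
  decoder-mediated state effect, empirically significant in this setup —
  and the "trait-only" world would not be a null for the transition
  contrast at all.
* **state world** — `trait_sd = 0`, `state_effect = 10`, with the full
  pathology spectral signature.

The full pipeline — synthesis, preprocessing, decoding, bias correction,
thresholds, longitudinal statistics — reports, in the trait world, a
non-significant moment-of-transition contrast and gap-difference test with
significant trait consistency, and in the state world the converse. A separate statistics-level battery (the decoder
replaced by effective age + Gaussian noise of realistic magnitude, 5 years)
verifies test calibration under the null in 3–7% of 500 replicates and
power ≥ 0.8 for the planted 10-year state effect with 50 transition
subjects, which would be prohibitively slow through the network.

## Numerical choices and degenerate inputs

* Threshold candidates never coincide with data values (midpoints), so the
  closed/open boundary convention cannot change a training-set BACC.
* `fit_bias()` requires ≥ 3 distinct CA values (rank error otherwise);
  constant gaps recover (0, 0, g) exactly.
* Brunner–Munzel errors on zero rank variability (fully separated samples)
  and warns below 10 per group.
* EDF I/O quantizes to 16 bits over ±1000 µV; round-trip error is bounded
  by half a quantization step and asserted in tests. Mixed per-signal rates
  and sub-second records are rejected rather than guessed at.
* The FFT resampler enforces conjugate symmetry at the shared Nyquist bin;
  equal input and output rates short-circuit to identity.
* Permutation seeds, cohort seeds and training seeds are all explicit
  arguments; nothing reads the global RNG state without restoring it.

## Known limitations

The synthetic EEG is a stand-in: how pathology manifests spectrally in real
clinical corpora is not quantitatively described by the source material,
and the planted slowing/attenuation model is a declared convention, not a
claim about any corpus. Decoding accuracies obtained here say nothing about
real-data accuracy. The desk-scale network is far smaller than a
production decoder; the amplitude-gradient maps are taken on standardized
inputs (the model's actual input space); and gradients are evaluated on a
non-overlapping crop grid by default (stride = receptive field) for
runtime, with stride 1 available.
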