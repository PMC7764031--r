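---
title: "Band-electrode selection by reversed correlation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-electrode selection by reversed correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegrca)
```

## The problem

Scalp EEG oversamples the brain: neighbouring electrodes record strongly
overlapping mixtures of the same cortical sources, so a 32-channel
recording decomposed into four frequency bands yields 128 band-electrode
feature streams of which only a handful carry independent information.
For affect monitoring (valence/arousal classification on the Russell
circumplex), working with all channels both wastes computation and
dilutes the discriminative signal with redundant noise.  `eegrca`
implements a complete workflow around an unsupervised answer to this
problem: rank band-electrode combinations by how *little* they correlate
with one another, keep the least redundant few, and verify the choice by
supervised cross-validation.

## The pipeline

1. **Preprocessing** (`trim_baseline()`, `resample_recording()`): remove
   the pre-trial baseline still attached to each trial and, if needed,
   decimate to the working rate with a zero-phase low-pass at 0.4 x the
   target rate beforehand.  128 Hz is the reference working rate; all
   four analysis bands sit below its Nyquist frequency.
2. **Band features** (`build_feature_matrix()`): each channel is
   band-pass filtered into theta (4-7 Hz), alpha (8-12), beta (13-30) and
   gamma (31-47); delta is excluded, as slow-wave power is dominated by
   drift and ocular residue.  Each band-passed trace is summarized by one
   value per non-overlapping one-second window.  Instances are these
   trial-seconds, pooled over trials and subjects (the subject-independent
   protocol); each inherits its trial's binary label.
3. **Selection** (`rca_select()`): the greedy reversed-correlation rule.
   The first feature chosen minimizes the mean absolute Pearson
   correlation to all other features; each later step adds the remaining
   feature with the lowest mean absolute correlation to the
   already-selected set.  Labels are never consulted.
4. **Evaluation** (`crossval_pipeline()`, `run_comparison_experiment()`):
   stratified 10-fold cross-validation of an RBF-kernel SVM, with the
   selection re-fitted inside every training fold, against the
   all-features baseline and seven fixed three-feature channel sets from
   the emotion literature (`get_fixed_set()`).

## The per-second statistic

The per-second summary is configurable (`band_power`, `mean_abs`,
`mean_raw`) with mean band power as the default.  The arithmetic mean of
a zero-mean band-passed signal is approximately zero and carries no
information, so the power reading of the per-second "mean statistic" is
the informative interpretation; `mean_abs` behaves almost identically in
practice (it is a robust amplitude reading), and `mean_raw` is retained
for completeness and for unfiltered inputs.

## Filtering choices

The band-pass is a 4th-order Butterworth applied forward and backward
(zero phase, squared magnitude response), with odd-reflection padding of
three filter orders at each edge.  Zero-phase filtering matters because
the features are windowed power estimates: a causal filter's group delay
would smear power across the one-second window boundaries.  The
forward-backward pass is implemented on top of `signal::butter`
coefficients with the recursion run in compiled code; a unit test checks
agreement with `signal::filtfilt` away from the edges.  Windows are
aligned to trial start and a trailing partial second is dropped, never
padded.

## The selection criterion

Redundancy is a magnitude notion - a perfectly anti-correlated channel is
fully redundant - so the criterion uses |Pearson| by default; a signed
mode exists for sensitivity analysis.  Zero-variance columns make Pearson
undefined and are removed (and reported) before selection rather than
assigned an arbitrary correlation.  Criterion ties within 1e-12 break
toward the lower column index, making the selection fully deterministic.
Because Pearson correlation is invariant under per-column positive affine
maps, so is the selection; because the labels are not an input, any
relabelling leaves it untouched.  Both properties are tested.

## The SVM protocol

Hyperparameters: cost C = 1 and kernel width gamma = 1/n_features on
standardized features (the inverse-dimension heuristic); both are exposed
as arguments.  Features are z-scored per fold with training-fold
statistics - raw band powers span orders of magnitude between bands, and
an RBF kernel on unstandardized powers is dominated by the largest-scale
feature.  Folds are stratified so every fold holds both classes.  The
fold partition is a deterministic function of (labels, k, seed) and is
shared by every channel set in one experiment, so set comparisons are
paired across folds.  Significance between two sets is assessed with a
two-sided Welch t-test on the per-fold accuracies (a paired variant is
available); with zero-variance fold vectors on both sides the p-value is
defined as 0 for different means and 1 for equal means.  The gain
convention is reference minus competitor, in percentage points, so a
positive gain means the reference (greedy) selection performed better.

Ratings on the 1-9 scale binarize at 4.5, with the boundary value mapped
to the *high* class: the low/high prose definitions only cover strict
inequalities, and a deterministic rule is required; `>= 4.5 -> 1` is the
declared convention and is tested.

## What the synthetic generator emulates

`synth_generate()` produces multi-channel trials whose structure mirrors
what makes real affective EEG hard:

* **Band-limited oscillatory activity**: each channel is a sum over the
  four bands of band-limited Gaussian noise (frequency-domain synthesis),
  not pure sinusoids, so per-second band powers fluctuate with the
  chi-square-like variance of real short-window estimates.
* **1/f background and sensor noise**: an aperiodic component with
  power ~ f^-1 plus white instrument noise.
* **Channel redundancy**: channels in a redundancy group share one latent
  source per band (mixing weight 0.9 by default), emulating volume
  conduction within a scalp region.
* **Global amplitude co-modulation**: a per-second log-normal gain
  (sd 0.35 on the log scale) multiplies all ongoing activity - bands and
  1/f background alike - in every channel, emulating slow vigilance
  fluctuations.  This shared envelope is what gives *every* pair of
  band-power features a positive baseline correlation, as in real
  recordings.
* **Planted evoked effects**: each `effect` entry replaces one named
  band-electrode stream with a private source whose amplitude is
  multiplied by `amplitude_ratio` on class-1 trials.  Evoked responses
  are stimulus-driven rather than vigilance-driven, so these sources
  couple to the global envelope with a reduced exponent
  (`effect_coupling = 0.30` versus 1 for ongoing activity).  This is also
  what makes the planted features *identifiable* to an unsupervised
  redundancy criterion: they are the streams least coupled to everything
  else, while remaining mutually decorrelated.
* **Ratings**: class-0 trials draw uniformly from [1, 4.3], class-1 from
  [4.7, 9], keeping a margin around the 4.5 threshold so binarization
  recovers the latent class exactly.

Defaults were fixed once against a brute-force re-implementation of the
greedy criterion and frozen: 2 subjects x 30 trials x 16 channels x 60 s
at 128 Hz with a 3 s baseline (3600 pooled instances), alpha-band effects
of ratio 1.12 at P8, AF4 and Cz, gain sd 0.35, coupling 0.30.  The
montage is a right-lateralized 16-channel subset chosen to contain every
channel used by the fixed literature sets; the feature-count check that
needs the full 32-channel montage constructs it explicitly.  Three
same-band planted sites are used because equal-band effects have equal
envelope loadings: an effect planted in a narrow band (theta) competes
against the wide-band features on an uneven footing, since the
time-bandwidth product of a one-second window makes narrow-band power
estimates intrinsically noisier and hence less correlated with everything.

With these defaults the planted triple is returned by `rca_select(fm, 3)`
in roughly nine out of ten seeds, and the 10-fold SVM on the selected
features scores ~0.60-0.63 against a shuffled-label chance band of
0.45-0.55.  The effect size deliberately sits well below ceiling: a large
planted effect makes the three planted features co-vary through the
shared class label, which *raises* their mutual correlation and hides
them from a redundancy-based selector - an instructive failure mode of
unsupervised selection that the generator can reproduce by raising
`amplitude_ratio`.

What the generator does **not** model: volume-conduction geometry (no
leadfield), artifacts (ocular, muscular, line noise), non-stationarity
across trials beyond the gain envelope, subject-specific spectra, or any
dependence between valence and arousal.  Passing tests on this generator
therefore demonstrate correctness of the pipeline's mechanics and the
selector's behaviour under a known ground truth - not performance on real
recordings.

## Clone fixtures

`make_clone_matrix()` builds the selection test fixture: groups of noisy
clones of shared latents plus singleton reference columns.  The reference
columns are *exactly* sample-decorrelated (centered, then orthogonalized
by QR).  This is deliberate: with merely independent draws, the sample
correlation between a clone and an already-selected reference column is
of order 1/sqrt(n), the same order as between two independent reference
columns, so "the algorithm returns the independent columns" would not be
a well-defined ground truth at finite n.  Exact orthogonality makes the
intended answer unambiguous at any noise level.

## Numerical and protocol details

* One master seed drives everything; stage substreams (synthesis,
  shuffling, folding) are derived from it so stages can be re-run in
  isolation.  The RNG state of the caller is always restored.
* Pipeline artifacts carry no timestamps; two runs with one seed are
  byte-identical, which is itself under test.
* The HDF5 container stores samples as 64-bit floats so a write/read
  round trip is bit-exact.  The EDF writer quantizes to the format's
  16-bit grid; its round trip is accurate to the quantization step.
* A chance-level estimate from a single cross-validated run has standard
  deviation ~0.02 on 1200 instances - about 1.3-1.5x the binomial level,
  because fold estimates are positively dependent.  The chance-band test
  therefore averages three independent label permutations per seed.
* Problem sizes in the test-suite (trial counts of 2-60, trial lengths of
  2-60 s) are chosen so the full suite exercises the same code paths as a
  full-size study while completing in minutes.

## Known limitations

* Only integer decimation factors are supported by
  `resample_recording()`; rational resampling would need a polyphase
  design that nothing in the workflow currently requires.
* The EDF reader handles the uniform-rate subset of the format (one
  sampling rate across signals, sidecar trial table); EDF+ annotations
  are not parsed.
* `selector_rca` refits the selection per fold, as the protocol demands;
  for very wide matrices this dominates runtime through the correlation
  matrix, which is O(p^2 n) per fold.
* The comparison experiment evaluates fixed sets only for the emotions
  their source studies addressed; the corresponding cells are reported
  blank, not zero.
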