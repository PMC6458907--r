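---
title: "Between-subject decoding of evoked fMRI responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-subject decoding of evoked fMRI responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painpattern)
```

## The scientific problem

Transient painful stimuli evoke reliable fMRI responses in a distributed set
of brain regions — thalamus, primary and secondary somatosensory cortices,
insula, anterior/mid-cingulate — often called the "pain matrix". The same
regions, however, also respond to intense or salient non-painful stimuli, so
regional activation alone cannot establish pain-selective processing. The
analysis this package implements asks a sharper question: after stimulus
intensity and saliency have been matched between painful and non-painful
conditions, does the *spatial pattern* of the evoked response still carry
information that distinguishes pain from touch, audition or vision — and does
that pattern generalize to people and scanners never seen in training?

The pipeline has five stages, each a module of the package:

1. **Masks** — boolean ROI algebra on voxel grids (union, intersection,
   morphological erosion, seeded subsampling, nearest-neighbour resampling,
   left/right splits) to build the analysis ROI, matched-size control masks
   and the 10 sub-regions.
2. **Matching** — psychophysical equating of conditions: subject-level
   counterbalancing of saliency differences, trial-level greedy pairing of
   perceived intensities, and certification of a match by a paired t-test
   plus the JZS Bayes factor in favor of the null.
3. **Preprocessing** — per-run motion regression, linear detrending and
   temporal z-scoring, extraction of peak-volume pattern samples, averaging
   to one pattern per subject and condition, optional ROI-wise
   normalization; alternatively, first-level GLM beta maps.
4. **Univariate control analysis** — per-ROI paired comparisons with
   max-statistic sign-flip permutation correction over the ROI family.
5. **MVPA** — leave-one-subject-out (LOSO) linear SVM classification with
   permutation-test null distributions, sensitivity maps, consistent-sign
   maps, median-split class construction, and cross-dataset train/test.

A synthetic-data generator emulating both experimental designs makes every
stage testable end to end without access to human imaging data.

## The decoder

The core estimator is a binary linear soft-margin support-vector machine.
For samples $x_i \in \mathbb{R}^V$ (one pattern of $V$ ROI voxels per
subject and condition) with labels $y_i \in \{\pm 1\}$, the primal problem is

$$\min_{w, b}\ \tfrac12 \lVert w \rVert^2 + C \sum_i \max(0,\, 1 - y_i(w^\top x_i + b)),$$

with $C = 1$ by default and no feature scaling beyond the stated ROI
normalization. The package solves the dual by sequential minimal
optimization (maximal-violating-pair working-set selection, unregularized
bias), implemented in compiled code so that the permutation suites — which
retrain the classifier hundreds of thousands of times — run in seconds. The
solver is validated in the test suite against two independent routes: the
libsvm implementation (e1071) and a direct interior-point solution of the
dual quadratic program (kernlab::ipop).

**Cross-validation.** Decoding is *between-subject*: each fold holds out all
samples of one subject, trains on the remaining $N-1$ subjects and scores the
held-out subject. Overall accuracy is the mean fold accuracy. A successful
LOSO classification therefore demonstrates a spatially consistent pattern
across people, not a subject-specific one.

**Inference.** The null distribution is built by randomly exchanging the
training labels within each fold (class counts preserved; held-out labels
untouched), retraining, and recording the mean fold accuracy — one value per
permutation, 5000 permutations in the canonical analysis. The p-value is the
proportion of null accuracies at or above the observed one; when no
permutation reaches it the report is the resolution bound
$p < 1/n_\text{perm}$ (0.0002 at 5000), with the flag `p_floored`. The
$(k+1)/(n+1)$ estimator is available but not the default, to match the
reporting convention of the original analyses.

**Sensitivity maps.** For a linear kernel the weight vector is itself a
voxel map: $w = \sum_i \alpha_i y_i x_i$. The package reports the mean of
the fold weight vectors (deterministic, no test-set leakage; a full-data
refit is a one-liner via `linear_svm()` if wanted). Positive weights mark
voxels with higher signal for the positive class — pain, by convention.
`consistent_sign_map()` intersects several classifications, keeping voxels
whose weight sign agrees everywhere.

## The matching procedures

Two procedures equate stimulus salience/intensity between conditions:

* `select_counterbalanced_subjects()` keeps every subject of the minority
  sign of the per-subject rating difference plus an equal-sized subset of
  the majority sign chosen (exhaustively up to 20 majority subjects) to
  minimize the absolute summed difference. Ties prefer the lower-variance
  subset, then lower subject ids. One caveat found while testing: when the
  minority side's summed difference exceeds what the entire majority side
  can offset, even the optimal equal-size selection balances worse than the
  full group. The function still returns the optimal subset (with its
  residual as an attribute); the property "selection never increases the
  mean difference" holds exactly when the optimal residual is at most
  $|\sum d| \cdot 2k/n$, and the tests assert it under that condition.
* `match_trials_greedy()` pairs each pain (laser) trial with the closest
  unused touch (electrical) trial within ±0.5 rating units, processing
  lasers in descending rating order, ties to the lower trial id, unmatched
  lasers discarded. Descending order with no reuse makes the procedure
  deterministic; the pairing is always admissible and inclusion-maximal
  (verified against exhaustive enumeration), though not guaranteed to be of
  maximum cardinality.

A match is certified by `validate_match()`: a two-tailed paired t-test and
the Jeffreys–Zellner–Siow Bayes factor $BF_{01}$, computed by adaptive
quadrature of the Rouder one-sample integral with a zero-centered Cauchy
prior on standardized effect size. The prior width defaults to **1.0**:
that is the width under which the package's reference values
($BF_{01}$ = 4.29 for $t=-0.09, n=10$; 3.91 for $t=0.04, n=8$; 3.27 for
$t=-1.46, n=51$) are reproduced, verified against a brute-force trapezoid
quadrature; the also-common 0.707 is available by argument.

```{r bf}
jzs_bf01(t = -0.09, n = 10)
jzs_bf01(t = -1.46, n = 51)
```

## The univariate control

`roi_family_test()` compares per-subject ROI mean signals between two
conditions with a paired t-test per ROI, and controls the family-wise error
over the 10-ROI family non-parametrically: under the null each subject's
difference vector has exchangeable sign, so the null of the maximum |t| over
the family is built from joint sign flips (exhaustive when $2^N$ does not
exceed the permutation budget, otherwise random). The original description
names a permutation correction but neither the pooled statistic nor the flip
scheme; max-|t| sign flipping is the standard familywise-controlling choice
and is declared in the result's `scheme` field rather than silently assumed.
Zero-variance ROIs are flagged and excluded from the max statistic.

## The synthetic-data generator

`generate_dataset()` simulates the two study designs with their published
parameters as defaults:

* *event-related, four modalities*: 14 subjects, 4 runs, 32 stimuli per run
  (8 per modality), inter-stimulus interval uniform in 10–19 s with fewer
  than 3 consecutive same-modality stimuli, TR 3 s, saliency ratings on a
  0–10 scale;
* *blocked, two modalities*: 51 subjects, 2 sessions, 3 pain and 3 touch
  blocks of 4 trials per session (25 s trial slots, stimulus onset uniform
  2–12 s into the slot), TR 0.8 s, intensity ratings centered on 3 (low)
  and 6 (high).

The signal model: each event contributes an impulse of amplitude
(modality amplitude + subject jitter) on a modality-specific spatial pattern
plus (shared amplitude × rating) on a common intensity-graded pattern, both
truncated Gaussian blobs inside the spherical ROI; impulses are convolved
with a canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6,
unit peak — one fixed analytic form keeps tests deterministic, since neither
FSL's nor SPM's exact variant is canonical here). With TR 3 s the response
peaks at the second volume after onset and with TR 0.8 s near the eighth,
matching the peak-extraction defaults. Noise is AR(1) plus white
(equal-variance components whose combined marginal sd is `noise_sd`),
spatially independent — the simplest model that exercises detrending and
normalization. Subject variability is additive Gaussian jitter on the
non-zero pattern amplitudes (floored at zero), not on pattern geometry,
because between-subject decoding presupposes coarse spatially aligned
patterns; setting an amplitude to zero therefore removes that signal
entirely, which the signal-free calibration relies on. Motion tables are
random walks (0.02 mm/volume drift; rotations scaled by 1/50) with optional
stimulus-locked and data-coupled artifact components so motion regression
has something real to remove.

Per-subject rating distributions are not published; the defaults (saliency
means 5.5/5.5/5.4/4.9, sd 2.2 for the event-related design; intensity means
3/6, sd 1 for the blocked design) take the printed group-level scales as
generator parameters and are documented as free choices. Auxiliary
saliency/valence columns are generated to match a target *pooled* sample
correlation with the intensity rating (targets 0.86 and −0.49 by default
when requested).

What the generator does *not* emulate: anatomy and registration error,
physiological noise, spatial noise correlations, scanner drifts beyond a
linear trend, and fine-grained (sub-voxel) pattern structure. Passing tests
on this generator therefore validate the *pipeline* — its statistics,
conventions and calibration — not the biological claim; real-data effect
sizes cannot be inferred from it.

## Fixed pipeline order and numerical choices

`build_modality_samples()` runs, per run: motion regression → linear
detrend + z-scoring → peak-volume extraction through the ROI →
trial averaging per modality and run → run averaging, giving one pattern per
subject × modality; `roi_normalize()` is applied when requested and is
mandatory for cross-dataset classification (enforced with an error). Whether
z-scoring preceded or followed motion regression is not documented for the
original analysis; regression-first is the package default (residuals are
then standardized exactly) and both stages can be toggled.

* Volume indexing: volume $i$ covers $[i\,\mathrm{TR}, (i+1)\,\mathrm{TR})$;
  the "$k$-th volume after onset" is $\lfloor \text{onset}/\mathrm{TR}
  \rfloor + k$.
* Degenerate (zero-variance or pure-trend) voxels become all-zero rather
  than NaN; constant pattern samples are an error for ROI normalization.
* Framewise displacement uses the standard 50 mm rotation radius; the
  stimulation window defaults to 2 volumes from the onset volume.
* Erosion defaults to 6-connectivity (face neighbours), which has a crisp
  analytic oracle (a cube of edge $n$ loses 2 voxels of edge per layer);
  the 3×3×3 box kernel of common tools is `connectivity = 26`. Voxels
  beyond the grid count as background.
* Left/right splits send world $x \le 0$ left, exactly as printed for the
  S1 split.
* Median-split ties go to "low"; class balancing removes the
  boundary-nearest samples deterministically (rating, then input order).
* The permutation exchange scheme preserves class counts by default;
  unrestricted Bernoulli relabeling is available via `perm_scheme`.
* The high-pass filtering of the original first-level GLMs is replaced by
  an intercept + linear drift regressor (Fourier/DCT filtering is out of
  scope); the GLM design is HRF-convolved condition sticks, their temporal
  derivatives, 6 motion columns, intercept and drift, with rank-deficiency
  reported by naming the collinear columns.

## Problem sizes used in the shipped checks

The calibration and recovery suites use scaled-down study conditions chosen
once: 12 subjects, a 500-voxel ROI on a 10³ grid, 2 runs of 4
stimuli/modality for calibration (200 replicates, 200 permutations each);
SNR 5 (amplitude 5, noise 1) for signal recovery; 10 + 10 subjects on a
shared or explicitly disjoint ground truth for cross-dataset transfer, with
the orthogonal case built from blob centres more than 6σ apart (truncated
support makes the patterns exactly orthogonal). Under these conditions the
signal-free mean LOSO accuracy sits within simulation error of 0.5, p-values
are calibrated (super-uniform), recovery runs at ceiling accuracy with
floored p, and transfer succeeds (accuracy > 0.9) exactly when the truth is
shared.

## Known limitations

* The generator's spatial patterns are smooth blobs; sensitivity-map
  recovery scores (top-decile Dice against truth) are easier than for
  fine-grained or anti-correlated real patterns.
* `resample_mask()` supports axis-aligned affines only — sufficient for
  every grid the package constructs, not for arbitrary oblique acquisitions.
* The greedy matcher is order-deterministic but not maximum-cardinality; an
  assignment-problem matcher would recover a few more pairs in adversarial
  rating configurations.
* Motion parameters are simulated or supplied, never estimated; spatial
  registration across subjects is assumed done (patterns are voxel-aligned).
```
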