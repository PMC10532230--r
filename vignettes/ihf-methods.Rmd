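---
title: "Intensity-histogram OOD detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-histogram OOD detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihf3d)
```

## The detection model

`ihf3d` treats out-of-distribution (OOD) detection as one-class novelty
detection on a very low-dimensional summary of each scan: its intensity
histogram. The working assumption is that clinically relevant
distribution shifts — a different scanner or protocol, a different
patient population, a different body region, or an acquisition artifact —
change the *distribution of voxel intensities*, even when they leave the
anatomy plausible. The converse does not hold: a shift that preserves the
intensity distribution exactly (for instance a purely geometric change at
matched tissue fractions) is invisible to this detector. That is a
deliberate trade: the method needs no trained network, no labels, and a
few dozen ID volumes.

The pipeline is:

1. **Standardise.** Resample to a common spacing (trilinear), clip
   intensities (CT: a fixed Hounsfield window; MRI: per-image percentile
   window, because MRI intensities are not calibrated across scanners),
   MinMax-scale to [0, 1]. After this step every volume is a probability
   distribution on [0, 1] plus geometry, and the geometry is discarded.
2. **Embed.** The m-bin intensity density `e(x)`, bins left-closed on
   `[i/m, (i+1)/m)` with the last bin closed at 1, values normalised so
   `sum(e)/m = 1`.
3. **Reduce.** PCA fitted once on the ID training embeddings, keeping the
   smallest k whose cumulative explained-variance ratio reaches `v`
   (capped at `min(n-1, m)`). PCA exists for numerical, not statistical,
   reasons: the Mahalanobis scorer must invert a covariance estimated
   from n embeddings in m dimensions, which is singular whenever n ≤ m.
4. **Score.** Mahalanobis distance to the training mean/covariance
   (population divisor n), or Euclidean distance to the nearest training
   embedding. Both are monotone "outlyingness" scores; neither is a
   calibrated probability.

An important consequence of step 1: MinMax scaling after clipping makes
the embedding exactly invariant to positive affine maps of the input
intensities (`a·x + b`, `a > 0`). Global gain/offset differences between
scanners are removed *by construction*; what remains detectable are
changes in the *shape* of the intensity distribution.

## Parameters that matter

| parameter | default | units | why this default |
|---|---|---|---|
| `target_spacing` | (1, 1, 1.5) | mm | common chest-CT / brain-MRI resampling target |
| `ct_window` | (−1350, 300) | HU | standard lung window; air to soft tissue |
| `mri_percentiles` | (1, 99) | % | robust per-image window for uncalibrated MRI |
| `m` | 150 | bins | fine enough to resolve tissue peaks at typical noise levels; quality is insensitive above ~100 |
| `v` | 0.9999 | — | keeps virtually all variance while removing the null space that breaks the covariance solve |
| `use_pca` | TRUE | — | off reproduces the "no PCA" variant; then the scorer sees raw m-dim embeddings |
| `scorer` | mahalanobis | — | adapts to correlated bins; `nn` makes no Gaussian-like assumption |
| ridge | 1e-6 · tr(Σ̂)/k | — | relative regularisation; scale-free, negligible (1e-6) perturbation of scores |

## Evaluation statistics

FPR@TPR95 accepts a sample when its score is ≤ τ, with τ the smallest
observed ID score accepting at least 95% of the ID test set (ties
accepted, so finite-sample ID acceptance is never below the target).
"Positives" are ID samples being preserved; FPR is the fraction of OOD
samples wrongly accepted, so random identically distributed scores give
FPR ≈ 0.95 and AUROC ≈ 0.5 — both are verified by simulation in the test
suite. Per-challenge FPRs in the benchmark harness share one τ from the
single ID test set, as a deployed detector would. AUROC uses the
all-pairs rank formulation with ties counted ½; the Fechner correlation
uses mean sign agreement of deviations from the mean, with zero
deviations contributing 0. The audit in the harness correlates
per-challenge FPR vectors (one entry per challenge, same order for every
method); correlating per-sample scores would be an alternative, but FPR
vectors are what the summary tables report.

The volume baseline needed a scalar score to enter the same machinery:
we use `|F̂(vol) − 0.5|` with the mid-rank empirical CDF
`F̂(v) = (#{x < v} + 0.5·#{x = v})/n`, which is 0 at the reference median
and 0.5 beyond either extreme, and is consistent with the two-sided
percentile decision rule (strict inequalities at the `q/2` and
`100 − q/2` linear-interpolation percentiles) away from percentile
boundary ties.

## The corruption simulators

Each corruption is a deterministic function of (volume, kind, severity,
seed) operating on raw intensities (before preprocessing), preserving
shape and spacing. Severity tables (levels 1–5) ship both in code
(`severity_params()`) and as `inst/extdata/severity_table.json`.
Magnitudes are relative where physical units are unavailable: local-noise
σ is a fraction of the volume's observed intensity range (unit range as a
fallback for constant volumes), K-space spike amplitude is a fraction of
the volume's intensity standard deviation. Levels were calibrated
perceptually once — level 1 barely visible on a phantom slice, level 5
heavily distorted — and are intended as fixed study conditions, not
tuning knobs. Outputs are deliberately not clipped to the input range:
noise and Fourier-domain artifacts legitimately overshoot, and clipping
would degenerate on constant inputs.

Two design notes. Anisotropy's default "linear" mode uses block-mean
downsampling with linear upsampling (an anti-aliased model of acquiring
at lower resolution); a "nearest" mode (subsample + replicate) exists and
is exactly invariant on slab-aligned piecewise-constant volumes, which
gives a sharp correctness oracle. Motion mixes the k-space of the
original with rigidly perturbed copies over contiguous frequency segments
along one axis — a standard discrete model of mid-acquisition movement;
ghosting is kept as a separate, cheaper kind (attenuated circular-shifted
copies) because the two artifacts look different and deserve separate
severity control.

## What the phantom generator emulates — and what it does not

A phantom is an ellipsoidal "body" plateau over a background plateau with
five flat-top (super-Gaussian) "lesion" blobs and i.i.d. Gaussian noise.
Per-volume variation comes from the body's centre and semi-axes (±5%),
blob placement, and the noise; the intensity *levels* are fixed. This
emulates the one property the detector relies on: a stable ID intensity
profile with controllable, clinically motivated departures:

- `intensity_shift` raises the body plateau only (an acquisition-protocol
  change of soft-tissue signal). Background and the blob class keep their
  levels deliberately: a shift of *all* levels is an affine map, which
  the preprocessing removes exactly, and would make the "OOD" arm
  mathematically identical to ID — a vacuous challenge.
- `contrast_change` applies a gamma curve to the noiseless field.
- `anatomy_change` swaps the ellipsoid for a superellipsoid (boxier body,
  different tissue fractions).

The flat-top blob class doubles as a *bright reference anchor*: it pins
the per-image 99th-percentile clipping bound, so a tissue shift moves the
body peak within a stable [p1, p99] frame instead of being re-normalised
away. This is the generator's one non-obvious calibration, chosen once so
that ID embeddings cluster tightly (mean pairwise distance several times
smaller than the distance to shifted arms) and frozen. With variable blob
count/size/amplitude the anchor itself fluctuates and ID spread grows —
a harder, noisier regime that small-scale phantoms (e.g. 32³) also
exhibit; the tests use the calibrated default scale for the separation
contracts and the small scale only for plumbing.

What passing tests on phantoms does **not** show: robustness to real
anatomy, multi-tissue histograms, bias fields, partial-volume effects, or
scanner noise spectra. The phantoms establish that the implementation is
correct and that the statistical machinery (thresholding, calibration,
severity trends) behaves as designed — not that IHF will reach any
particular FPR on clinical data.

## Numerical choices and degenerate inputs

- Resampling output shape is `round(n·s_in/s_target)`, rounding half away
  from zero, minimum 1; samples beyond the input grid clamp to the border.
  Constant volumes resample to constants (up to float round-off).
- Constant volumes MinMax-scale to all zeros (keeping the histogram well
  defined) rather than erroring.
- Percentiles everywhere use linear interpolation between order
  statistics (R type 7).
- The covariance uses divisor n (population form) to match the estimator
  the scores are defined with; the trace identity "mean squared train
  Mahalanobis distance = k" then holds exactly and is used as a pipeline
  test.
- Zero-variance training data (e.g. identical volumes) yields a
  ridge-only covariance `1e-6·I` and a single arbitrary PCA direction —
  scoring remains defined.
- PCA component signs are canonicalised (largest loading positive) so
  fits are bit-reproducible; there is no other hidden randomness in the
  fit path.
- Score ties at the FPR threshold are accepted (≤ τ), guaranteeing ID
  acceptance ≥ the target TPR on finite samples.
- Per-volume seeds in `build_fixture()` are drawn without replacement
  from the base-seeded stream: arms never share a seed and different base
  seeds give uncorrelated fixtures.

## Problem sizes

The shipped tests and the acceptance script use 64 × 64 × 48 phantoms
with 30–50 training volumes and 20–30 volumes per test arm, and 10–20
seeds per stochastic property; these sizes were chosen so the whole suite
runs in about a minute while keeping the statistical checks meaningful
(e.g. the null-FPR check uses 2000 scores per arm across 20 repetitions,
and the chance-level benchmark arm uses 200 volumes per side). One
caveat stated plainly: a 95th-percentile threshold estimated from 30 ID
scores has substantial sampling noise (the expected null FPR is
29/31 ≈ 0.935 with sd ≈ 0.06), so control-arm FPR values on single small
fixtures should be read with that width in mind.

## Known limitations

- Histograms discard all spatial information; focal lesions that barely
  move the global histogram are out of reach (the local-noise corruption
  at low severity is the hardest synthetic kind for exactly this reason).
- Per-image percentile clipping (MRI path) absorbs part of any intensity
  shift; detectability depends on the distribution's shape changing, not
  its location.
- The Mahalanobis scorer assumes an ellipsoidal ID cloud in the reduced
  space; heavy-tailed score distributions make its small-sample FPR
  thresholds noisy. The NN scorer avoids the shape assumption at the cost
  of more variance with few training volumes.
- The motion and ghosting simulators are phenomenological k-space models,
  not sequence-accurate MRI simulation; CT artifacts are modelled in the
  image domain, not the sinogram domain.
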