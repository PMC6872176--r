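---
title: "Benchmarking task-fMRI detection performance on synthetic BOLD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking task-fMRI detection performance on synthetic BOLD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmriseqbench)
```

## What the package models

fMRI acquisition schemes differ most consequentially in their *noise
structure*: roughly, accelerated 2D multiband sequences tend to be dominated
by thermal (receiver) noise, whereas 3D-EPI readouts at matched resolution
are more exposed to physiological fluctuations — cardiac, respiratory and
slow vascular signals that are spatially structured and shared across
voxels. Whether one scheme detects task activation better than another is a
question about the whole chain: noise → preprocessing → GLM inference →
thresholding. `fmriseqbench` implements that chain on synthetic data so each
link can be studied in isolation and in combination.

The forward model for a voxel $v$ with baseline $b_v$ is

$$ y_v(t) = b_v\Big[1 + \sum_c e_c\, \mathbf 1\{v \in \mathrm{ROI}_c\}\, x_c(t)\Big]
  + d_v(t) + \sum_k \ell_k(v)\, g_k(t) + \varepsilon_v(t), $$

with $e_c$ the fractional effect size of contrast $c$ (0.01 = 1% signal
change), $x_c$ the canonical-HRF-convolved stimulus train of the conditions
driving that region, $d_v$ a slow per-voxel polynomial drift, $g_k$
unit-variance shared "physiological" components with tissue-weighted
loadings $\ell_k$, and $\varepsilon_v$ AR(1) Gaussian thermal noise. The
baseline is 100 inside the brain so effect sizes read directly as percent
signal change, and the activation regressors are built on the same fine
time grid as the analysis design matrix — with zero noise, least squares
recovers $\beta = b\,e_c$ to machine precision, which the test suite
asserts.

## The paradigm and the phantom

The simulated run mimics a fast event-related multi-task localizer: 5:20
min (320 s, 267 volumes at TR 1.2 s), ten condition types (sentence reading
and listening, visually and auditorily cued mental calculation, left/right
button presses under visual or auditory cueing, and two checkerboard
variants), three events per condition by default, pseudo-randomized order
with a 2 s minimum gap and jittered onsets. The published study that uses
this paradigm does not print its literal event schedule, so the generator
reproduces the paradigm's statistical structure (counts, gaps, duration)
rather than a specific timetable; counts and gaps are configuration.

The phantom is a spherical head: a CSF core (standing in for the
ventricles), a white-matter shell, and a grey-matter rind, with piecewise
linear transitions. Each class reaches probability 1 in its interior
deliberately, because anatomical CompCor takes its noise ROIs at tissue
probability 1. One compact spherical ROI per benchmark contrast is placed
on the grey-matter rind at evenly spaced azimuths with seeded jitter; ROIs
are disjoint by construction and always inside the ≥ 5% grey-matter band.
There is no motion, no distortion and no k-space physics — the phantom's
purpose is detection scoring, not image realism.

## Noise profiles

Two presets encode the qualitative contrast the benchmark is about, with
all amplitudes as fractions of baseline:

| profile      | thermal sd | AR(1) ρ | physio (gm/wm/csf)    | drift |
|--------------|-----------:|--------:|-----------------------|------:|
| `sms_like`   | 0.020      | 0.2     | 0.002 / 0.006 / 0.008 | 0.01  |
| `epi3d_like` | 0.012      | 0.3     | 0.010 / 0.020 / 0.030 | 0.01  |

These values were chosen once, on two grounds: (i) grey-matter temporal SNR
in the 40–80 range, the order observed for sub-millimetre-to-1.6 mm
protocols at high field; and (ii) the defining property that at comparable
total variance the `epi3d_like` profile puts a strictly larger fraction of
it into the shared physiological components (dominant in WM/CSF, present in
grey matter), while `sms_like` is thermal-dominated. The physiological
components are a respiratory-like sinusoid (~0.3 Hz), a cardiac-aliased
sinusoid (~1.05 Hz, aliased by the 1.2 s TR) and a smooth random walk. The
true spectrum of physiological noise under any particular sequence is not
characterised in the literature this package draws on; these frequencies
are assumptions, and CompCor's ability to remove the components depends
only on their low-rank shared structure, not on the exact frequencies.

Drift is a second-order polynomial per voxel with amplitude 1% of baseline
— enough to matter, and entirely removable by the 128 s high-pass, which it
exists to exercise.

## The analysis chain

* **Smoothing**: separable Gaussian, σ = FWHM/(2√(2 ln 2)) per axis,
  zero-padded boundaries (simple and bit-reproducible), FWHM 5 mm default.
* **Grey band**: analysis restricted to voxels with grey-matter probability
  ≥ 5%, boundary inclusive.
* **High-pass**: DCT basis with `K = floor(2·N·TR/cutoff)` columns
  (the convention of the standard SPM-style analysis), cutoff 128 s;
  `(267, 1.2, 128)` gives exactly 5 columns. Temporal SNR uses the same
  basis for detrending — one definition of "detrended" throughout the
  package, since the source methodology computes tSNR "after detrending"
  without fixing the method — and is computed on *unsmoothed* data.
* **Design**: canonical double-gamma HRF (peak 6 s, undershoot 16 s, unit
  dispersions, ratio 1/6, 32 s kernel, 0.1 s fine grid) plus its finite-
  difference temporal derivative per condition, sampled at `t = i·TR`;
  drift columns; optional nuisance columns; a constant. Rank deficiency is
  an error that names the collinear columns.
* **CompCor**: voxel series inside the WM (or CSF) probability-1 mask are
  drift-projected, variance-normalised, and the top left singular vectors
  (5 WM + 3 CSF by default) enter the design as nuisance regressors.
* **Whitening**: `ols` (none), `ar1` (two-pass: OLS residuals → pooled
  lag-1 autocorrelation → AR(1) whitening transform → OLS), or `extended`
  (the same scheme with a pooled Yule-Walker AR(3), a documented stand-in
  for multi-component noise models such as SPM's FAST; it exercises the
  same pipeline branch but is not claimed to reproduce FAST numerically).
  The pooled estimate is *bias-corrected*: OLS residuals understate the
  noise autocorrelation because projection onto smooth design columns
  (HRF regressors, DCT drift) removes autocorrelated variance — with this
  design, raw pooled lag-1 reads ≈ 0.28 when the truth is 0.4. `fit_glm`
  therefore inverts the expected residual autocorrelation map
  $\rho_{obs}(\rho) = \mathrm{tr}(B M V(\rho) M)/\mathrm{tr}(M V(\rho) M)$
  (a method-of-moments correction playing the role ReML plays in SPM)
  before building the whitening transform. This is what makes the AR(1)
  arm's type-I error nominal in the acceptance checks.
* **Inference**: per-voxel t statistics
  $t = c^\top\hat\beta / \sqrt{\hat\sigma^2\, c^\top(X_w^\top X_w)^{-1}c}$;
  the mean-signal t is the contrast on the constant column. p-values are
  **one-sided** upper-tail by default: the referenced analysis software
  reports one-sided t contrasts and every catalogue contrast is directional
  (e.g. audio−video); the two-sided option exists.

## Detection scoring

"Activated" means `p < α` with *strict* inequality (matching "p < 0.001"
notation); ties break toward non-activation. Sensitivity and specificity
are counted against the phantom's ground-truth ROI inside an explicit
analysis mask — the grey band by default; the mask is an argument because
the choice of specificity denominator is a genuine analytic degree of
freedom. The ROC is swept over 200 thresholds (100 geometric from 1e-6 to
0.01, then linear to 0.5 — dense where the curve bends) with anchors (0,0)
and (1,1); an α = 0 endpoint is degenerate (strictly nothing passes), so
the anchor replaces it. When the grid contains every distinct p-value the
trapezoidal AUC is *exactly* the Mann–Whitney statistic, ties counted 1/2 —
a property the tests verify against a brute-force pairwise oracle. d′ is
computed at α = 0.001; degenerate rates of 0 or 1 are clipped to 1/(2n)
only on request (`clip_counts`), never silently.

Aggregation follows the study design: contrasts are averaged within
subject at each threshold, giving one ROC/AUC per subject, then AUC and d′
are summarised as mean ± sd over subjects. The four sensorimotor contrasts
(video−audio, audio−video, left−right, right−left press) are the benchmark
set; the higher-level contrasts (computation−sentences,
sentences−checkerboard) are simulated and testable but not part of the
default score, mirroring their higher inter-subject variability in real
cohorts.

## What the defaults compute, and at what scale

`experiment_config()` defaults encode the study conditions: 10 subjects,
20³ voxels at 2 mm, 267 volumes at TR 1.2 s, 1% effect, both noise
profiles, AR(1) whitening, CompCor on/off, 5 mm smoothing, p < 0.001. The
test suite runs a 5-subject version of this experiment (a few seconds per
arm); the phantom is shared across subjects — reference ROIs are common
ground truth — while paradigm and noise realisations differ per subject
through derived seeds (`master + subject`).

Running it shows the headline qualitative pattern: removing the CompCor
regressors barely moves d′ on `sms_like` data but collapses it on
`epi3d_like` data, because regressing signal-dependent components out of
thermal noise cannot reduce variance, while removing shared physiological
components can.

## What passing tests do and do not show

The generator reproduces the *statistical* structure the pipeline assumes:
HRF-shaped activation confined to known ROIs, stationary AR(1) thermal
noise, low-rank shared physiological noise, smooth drift. Real data violate
all of these to some degree — motion, spatially varying autocorrelation,
non-stationary physiology, HRF variability across regions and subjects —
and none of those violations are modelled. Green tests therefore certify
the *method's* calibration (type-I error, amplitude recovery, ROC/AUC/d′
arithmetic) and the *relative* behaviour of analysis choices under the
stated noise models, not absolute performance numbers on scanner data.
Published in-vivo values (AUC ≈ 0.70 at 7T against 3T-defined reference
ROIs) include inter-subject ROI mismatch that a phantom with exact ground
truth cannot and should not reproduce.

## Numerical choices and degenerate inputs

* Seeded determinism everywhere: every stochastic operation is a pure
  function of its arguments including the seed, and restores the caller's
  RNG state.
* tSNR at zero temporal sd is undefined (`NA`), carried explicitly.
* Smoothing with FWHM 0 is the identity; kernels are truncated at 4σ and
  renormalised, so interior sums are conserved to 1e-8.
* The DCT basis refuses cutoffs ≤ 2·TR (aliasing).
* `estimate_ar1` clips to [0, 0.99]; negative pooled autocorrelation maps
  to 0 (no whitening) rather than to an invalid transform.
* Whitened fits of all-zero voxels yield zero residual variance and `NA`
  t-values, flagged, never ±Inf.
* CompCor refuses masks whose series are constant after drift removal and
  component counts exceeding `min(n_volumes − 1, mask size)`; returned
  components have a deterministic sign convention (largest element
  positive).
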