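# fmriseqbench

Detection-theory benchmarking of task-fMRI acquisition schemes on fully
synthetic BOLD data.

## The problem

Choosing between fMRI pulse sequences (for example a thermal-noise-dominated
simultaneous-multi-slice 2D-EPI versus a 3D-EPI that is more sensitive to
physiological noise) is ultimately a *detection* question: at a given
significance threshold, how well does the analysis pipeline recover the
voxels that are truly active while rejecting the ones that are not?
`fmriseqbench` implements that evaluation end to end for researchers who
want to study how noise structure, prewhitening and nuisance regression
interact with detection performance — without needing scanner data. It
provides:

* a **synthetic-data module**: a fast event-related multi-task "localizer"
  paradigm (ten condition types over a 5:20 min run), a digital head phantom
  with grey-matter/white-matter/CSF structure and ground-truth activation
  ROIs, and a BOLD forward model with canonical-HRF activation, slow drift,
  AR(1)-correlated thermal noise and shared low-rank physiological noise
  loaded on WM/CSF;
* a **preprocessing module**: Gaussian smoothing, temporal SNR, grey-matter
  band masking and a discrete-cosine high-pass drift basis (128 s cut-off);
* a **GLM module**: canonical double-gamma HRF plus temporal derivative per
  condition, anatomical CompCor nuisance regressors (3 CSF + 5 WM
  components), and per-voxel least squares under OLS, AR(1) or higher-order
  autoregressive prewhitening with contrast t-maps — including the
  mean-signal t-score, which is sensitive to unmodelled temporal
  correlation;
* a **benchmark module**: sensitivity `TP/|ROI|` and specificity
  `1 − FP/|non-ROI|` against reference ROIs, ROC curves over significance
  thresholds in (0, 0.5], trapezoidal AUC, and the detection-theory index

  ```
  d' = Z(sensitivity) − Z(1 − specificity)
  ```

  with `Z` the standard-normal quantile function, evaluated by default at
  p < 0.001 (uncorrected);
* a **runner**: `run_experiment()` simulates a cohort, analyses every
  (profile × whitening × nuisance) arm and aggregates AUC and d′ across
  subjects, the aggregation done per subject first and then averaged.

## Worked example

```r
library(fmriseqbench)

phantom <- generate_phantom(c(20L, 20L, 20L), 2, sensorimotor_contrasts(),
                            seed = 1)
events  <- generate_paradigm(320, 3, min_gap = 2, seed = 2)
profile <- noise_profile("epi3d_like")
bold <- simulate_bold(phantom, events,
                      effect_size = setNames(rep(0.01, 4),
                                             sensorimotor_contrasts()),
                      profile, n_volumes = 267, TR = 1.2, seed = 3)
bold  <- gaussian_smooth(bold, fwhm = 5)
drift <- dct_highpass_basis(267, 1.2, cutoff = 128)
nuis  <- cbind(compcor_regressors(bold, phantom$csf >= 1, 3, drift),
               compcor_regressors(bold, phantom$wm  >= 1, 5, drift))
colnames(nuis) <- paste0("nuisance_", 1:8)
X   <- build_design_matrix(events, 267, 1.2, drift = drift, nuisance = nuis)
fit <- fit_glm(bold, X, whitening = "ar1")
#> rho-hat: 0.306   dof: 233

pmap <- pmap_from_tmap(contrast_tmap(fit, X, "left_minus_right"))
band <- grey_band_mask(phantom$gm) & phantom$brain_mask
roc_curve(pmap, phantom$roi$left_minus_right, band)
#> roc_result: 201 thresholds, AUC 0.9968 (ROI 32, non-ROI 2216)

pt <- sens_spec(pmap, phantom$roi$left_minus_right, band, 0.001)
dprime(pt, clip_counts = TRUE)$dprime
#> sens 1.000, spec 0.976 at p < 0.001; d' = 4.13
```

The simulated 1% signal change in the left-press ROI is detected with
sensitivity 1 at p < 0.001 while 97.6% of the grey-matter band outside the
ROI stays below threshold; the ROC over the full threshold sweep has AUC
0.997. (A perfect classifier has AUC 1; a random one 0.5.) With the
physiological-noise-dominated `"epi3d_like"` profile, dropping the CompCor
regressors collapses d′ by around 3 units, while on the thermal-dominated
`"sms_like"` profile the change is small — the structured-noise regressors
only help where structured noise dominates.

See `vignettes/detection-benchmarking.Rmd` for the model, its assumptions
and the numerical choices.

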