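Package: fmriseqbench
Title: Detection-Theory Benchmarking of Task-fMRI Acquisition Schemes on Synthetic BOLD Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fast event-related task-fMRI time series with controlled
    activation, drift, autocorrelated thermal noise and low-rank physiological
    noise on a digital phantom; fits a mass-univariate general linear model with
    canonical HRF plus temporal-derivative regressors, discrete-cosine high-pass
    drift terms, anatomical CompCor nuisance regressors and AR(1) or higher-order
    autoregressive prewhitening; and scores voxelwise detection of activation
    against reference regions of interest using sensitivity, specificity, ROC
    curves, AUC and d-prime. Includes a one-command experiment runner that
    compares thermal-noise-dominated and physiological-noise-dominated
    acquisition profiles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
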