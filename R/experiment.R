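#' Configure a sequence-comparison experiment
#'
#' Bundles the study conditions for [run_experiment()]: a 5:20 min fast
#' event-related run at TR 1.2 s (267 volumes), ten conditions, two noise
#' profiles, AR(1) prewhitening, CompCor on/off, and detection scoring at
#' p < 0.001 on the four sensorimotor contrasts. Defaults reproduce the
#' simulated study at desk scale; per-subject seeds are `seed + subject`.
#'
#' @param n_subjects Number of simulated subjects.
#' @param grid Phantom dimensions in voxels.
#' @param voxel_size Voxel size in mm.
#' @param TR Repetition time (s).
#' @param n_volumes Volumes per run.
#' @param run_duration Run length (s).
#' @param events_per_condition Events of each condition per run.
#' @param min_gap Minimum inter-event gap (s).
#' @param effect Fractional activation effect applied to every benchmark
#'   contrast ROI (0.01 = 1% signal change).
#' @param profiles Noise profile names to compare.
#' @param whitening Whitening models to run.
#' @param nuisance Logical vector: arms with/without CompCor regressors.
#' @param fwhm Spatial smoothing FWHM in mm.
#' @param cutoff High-pass cut-off period (s).
#' @param n_compcor_csf,n_compcor_wm CompCor components per noise tissue.
#' @param alpha Significance threshold for d' (default 0.001).
#' @param alpha_grid ROC threshold grid.
#' @param contrasts Benchmark contrast names (ROIs are placed for these).
#' @param seed Master seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10, grid = c(20L, 20L, 20L),
                              voxel_size = 2, TR = 1.2, n_volumes = 267,
                              run_duration = 320, events_per_condition = 3,
                              min_gap = 2, effect = 0.01,
                              profiles = c("sms_like", "epi3d_like"),
                              whitening = "ar1",
                              nuisance = c(TRUE, FALSE),
                              fwhm = 5, cutoff = 128,
                              n_compcor_csf = 3, n_compcor_wm = 5,
                              alpha = 0.001,
                              alpha_grid = default_alpha_grid(),
                              contrasts = sensorimotor_contrasts(),
                              seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects), grid = as.integer(grid),
              voxel_size = voxel_size, TR = TR,
              n_volumes = as.integer(n_volumes),
              run_duration = run_duration,
              events_per_condition = events_per_condition,
              min_gap = min_gap, effect = effect, profiles = profiles,
              whitening = whitening, nuisance = nuisance, fwhm = fwhm,
              cutoff = cutoff, n_compcor_csf = as.integer(n_compcor_csf),
              n_compcor_wm = as.integer(n_compcor_wm), alpha = alpha,
              alpha_grid = alpha_grid, contrasts = contrasts,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1L) stop("need at least one subject", call. = FALSE)
  if (cfg$n_volumes * TR < run_duration)
    stop("n_volumes * TR must cover run_duration", call. = FALSE)
  bad <- setdiff(profiles, c("sms_like", "epi3d_like"))
  if (length(bad))
    stop("undefined noise profile(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(cfg) <- "experiment_config"
  cfg
}

#' Run the full simulation-analysis-benchmark experiment
#'
#' For every subject and noise profile: simulate a localizer run on a shared
#' phantom (ROI geometry common to all subjects, noise realisations seeded
#' per subject), smooth, compute tSNR, build the design (canonical HRF +
#' derivative per condition, DCT drift, optional CompCor regressors from
#' WM/CSF at tissue probability 1), fit the GLM under each whitening model,
#' derive t-maps for the six localizer contrasts plus the mean-signal
#' contrast, and score the benchmark contrasts against the phantom ROIs
#' within the grey-matter band. Results are aggregated over subjects per
#' (profile, whitening, nuisance) arm.
#'
#' @param config An [experiment_config()].
#' @param out Optional directory; when given, the report is written there as
#'   `report.json`.
#' @return A list of class `experiment_report` with `config` (scalar fields),
#'   and `arms`: one element per arm holding `tsnr_mean`, `t_mean_signal`,
#'   `auc_mean`, `auc_sd`, `dprime_mean`, `dprime_sd` and per-subject values.
#' @export
#' @examples
#' \donttest{
#' cfg <- experiment_config(n_subjects = 1, grid = c(12L, 12L, 12L),
#'                          n_volumes = 60, run_duration = 60,
#'                          events_per_condition = 1, fwhm = 0)
#' rep <- run_experiment(cfg)
#' }
run_experiment <- function(config, out = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  phantom <- generate_phantom(cfg$grid, cfg$voxel_size, cfg$contrasts,
                              seed = cfg$seed)
  gm_band <- grey_band_mask(phantom$gm, 0.05) & phantom$brain_mask
  csf_mask <- phantom$csf >= 1
  wm_mask <- phantom$wm >= 1
  effects <- stats::setNames(rep(cfg$effect, length(cfg$contrasts)),
                             cfg$contrasts)
  drift <- dct_highpass_basis(cfg$n_volumes, cfg$TR, cfg$cutoff)
  arms <- list()

  for (prof_name in cfg$profiles) {
    profile <- noise_profile(prof_name)
    per_subject <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      step <- sprintf("subject %d, profile %s", s, prof_name)
      res <- tryCatch({
        events <- generate_paradigm(cfg$run_duration,
                                    cfg$events_per_condition,
                                    min_gap = cfg$min_gap,
                                    seed = cfg$seed + s)
        vol <- simulate_bold(phantom, events, effects, profile,
                             cfg$n_volumes, cfg$TR,
                             seed = cfg$seed + 101L * s +
                               7919L * match(prof_name, cfg$profiles))
        vol_s <- gaussian_smooth(vol, cfg$fwhm)
        # raw tSNR: detrended but unsmoothed series
        tsnr <- compute_tsnr(vol, detrend_cutoff = cfg$cutoff)
        nuis <- cbind(
          compcor_regressors(vol, csf_mask, cfg$n_compcor_csf, drift = drift),
          compcor_regressors(vol, wm_mask, cfg$n_compcor_wm, drift = drift))
        colnames(nuis) <- paste0("nuisance_", seq_len(ncol(nuis)))
        list(events = events, vol = vol_s, tsnr = tsnr, nuisance = nuis)
      }, error = function(e)
        stop(sprintf("stage 'simulate' failed for %s: %s", step,
                     conditionMessage(e)), call. = FALSE))
      per_subject[[s]] <- res
    }

    for (wh in cfg$whitening) for (use_nuis in cfg$nuisance) {
      cells <- list()
      tsnr_subj <- t_mean_subj <- numeric(cfg$n_subjects)
      for (s in seq_len(cfg$n_subjects)) {
        ps <- per_subject[[s]]
        step <- sprintf("subject %d, arm %s/%s/nuisance=%s", s, prof_name,
                        wh, use_nuis)
        fit_res <- tryCatch({
          X <- build_design_matrix(ps$events, cfg$n_volumes, cfg$TR,
                                   drift = drift,
                                   nuisance = if (use_nuis) ps$nuisance)
          fit <- fit_glm(ps$vol, X, whitening = wh,
                         mask = as.vector(gm_band))
          tmaps <- lapply(c(names(localizer_contrasts()), "mean_signal"),
                          function(nm) contrast_tmap(fit, X, nm))
          names(tmaps) <- c(names(localizer_contrasts()), "mean_signal")
          list(X = X, fit = fit, tmaps = tmaps)
        }, error = function(e)
          stop(sprintf("stage 'fit' failed for %s: %s", step,
                       conditionMessage(e)), call. = FALSE))
        tsnr_subj[s] <- mean(ps$tsnr$data[gm_band], na.rm = TRUE)
        t_mean_subj[s] <-
          mean(fit_res$tmaps$mean_signal$data[gm_band], na.rm = TRUE)
        for (cn in cfg$contrasts) {
          cell <- tryCatch({
            pmap <- pmap_from_tmap(fit_res$tmaps[[cn]])
            roc <- roc_curve(pmap, phantom$roi[[cn]], gm_band,
                             cfg$alpha_grid)
            dp <- dprime(sens_spec(pmap, phantom$roi[[cn]], gm_band,
                                   cfg$alpha),
                         clip_counts = TRUE)
            list(subject = s, contrast = cn, roc = roc, dprime = dp)
          }, error = function(e)
            stop(sprintf("stage 'benchmark' failed for %s (%s): %s", step,
                         cn, conditionMessage(e)), call. = FALSE))
          cells[[length(cells) + 1L]] <- cell
        }
      }
      agg <- aggregate_benchmark(cells)
      arm_name <- sprintf("%s.%s.%s", prof_name, wh,
                          if (use_nuis) "compcor" else "nonuisance")
      arms[[arm_name]] <- list(
        profile = prof_name, whitening = wh, nuisance = use_nuis,
        tsnr_mean = mean(tsnr_subj), tsnr_sd = stats::sd(tsnr_subj),
        t_mean_signal = mean(t_mean_subj),
        t_mean_signal_sd = stats::sd(t_mean_subj),
        auc_mean = agg$auc_mean, auc_sd = agg$auc_sd,
        dprime_mean = agg$dprime_mean, dprime_sd = agg$dprime_sd,
        per_subject = agg$per_subject,
        sensitivity_at_alpha = mean(vapply(cells, function(cl) {
          i <- which.min(abs(cl$roc$alpha_grid - cfg$alpha))
          cl$roc$points$sensitivity[i]
        }, 0)),
        specificity_at_alpha = mean(vapply(cells, function(cl) {
          i <- which.min(abs(cl$roc$alpha_grid - cfg$alpha))
          cl$roc$points$specificity[i]
        }, 0)))
    }
  }

  report <- structure(list(
    config = cfg[c("n_subjects", "grid", "voxel_size", "TR", "n_volumes",
                   "run_duration", "events_per_condition", "effect",
                   "profiles", "whitening", "nuisance", "fwhm", "cutoff",
                   "alpha", "seed")],
    arms = arms), class = "experiment_report")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_report(unclass_report(report), file.path(out, "report.json"))
  }
  report
}

# strip S3 classes / data frames for clean JSON serialisation
unclass_report <- function(report) {
  walk <- function(x) {
    if (is.data.frame(x)) return(lapply(as.list(x), unname))
    if (is.list(x)) return(lapply(x, walk))
    x
  }
  walk(unclass(report))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: %d subject(s), %d arm(s)\n",
              x$config$n_subjects, length(x$arms)))
  for (nm in names(x$arms)) {
    a <- x$arms[[nm]]
    cat(sprintf("  %-30s tSNR %6.1f  t(mean) %7.1f  AUC %.3f  d' %6.3f\n",
                nm, a$tsnr_mean, a$t_mean_signal, a$auc_mean, a$dprime_mean))
  }
  invisible(x)
}
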