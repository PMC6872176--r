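#' Simulate BOLD time series on a phantom
#'
#' Forward model, per voxel:
#' \deqn{y(t) = b \,[1 + \sum_c e_c \, 1\{v \in ROI_c\} \, x_c(t)] + d(t) +
#'   \sum_k \ell_k(v)\, g_k(t) + \epsilon(t)}
#' where `b` is the baseline, `e_c` the fractional effect size of contrast
#' `c`, `x_c` the sum of HRF-convolved boxcars of the conditions driving that
#' contrast's region, `d` a slow polynomial drift, `g_k` unit-variance
#' physiological components with tissue-weighted loadings `l_k` (largest in
#' WM/CSF), and `eps` AR(1)-correlated Gaussian thermal noise. The activation
#' regressors are built on the same fine time grid as the GLM design, so with
#' zero noise the GLM recovers `beta = b * e_c` exactly.
#'
#' @param phantom A [generate_phantom()] phantom.
#' @param events An [event_table].
#' @param effect_size Named numeric vector, fraction of baseline per contrast;
#'   names must match the phantom's ROI names.
#' @param profile A [noise_profile()].
#' @param n_volumes Number of volumes (>= 2).
#' @param TR Repetition time in seconds.
#' @param seed Integer seed; identical seeds give identical series.
#' @param hrf An [hrf_spec].
#' @param respond Optional named list mapping each contrast to the condition
#'   labels that drive its ROI; defaults to the positive-weight conditions of
#'   the catalogue contrast of the same name, or all conditions present for
#'   unknown names.
#' @return A [volume4d] with the phantom's brain mask attached.
#' @export
#' @examples
#' ph <- generate_phantom(c(12, 12, 12), 2, "video_minus_audio", seed = 1)
#' ev <- generate_paradigm(60, 1, min_gap = 2, seed = 1)
#' prof <- noise_profile("sms_like")
#' vol <- simulate_bold(ph, ev, c(video_minus_audio = 0.02), prof,
#'                      n_volumes = 60, TR = 1.2, seed = 1)
simulate_bold <- function(phantom, events, effect_size, profile, n_volumes,
                          TR, seed = 1, hrf = hrf_spec(), respond = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(events, "event_table"),
            inherits(profile, "noise_profile"))
  assert_scalar_num(n_volumes, "n_volumes", lower = 2)
  assert_scalar_num(TR, "TR", lower = 0, strict_lower = TRUE)
  n <- as.integer(n_volumes)
  if (nrow(events) &&
      max(events$onset + events$duration) > n * TR)
    stop("events extend beyond the run (n_volumes * TR)", call. = FALSE)
  if (length(effect_size) && is.null(names(effect_size)))
    stop("effect_size must be a named vector keyed by contrast", call. = FALSE)
  unknown <- setdiff(names(effect_size), names(phantom$roi))
  if (length(unknown))
    stop("effect_size names without a phantom ROI: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(effect_size < 0))
    stop("effect sizes must be >= 0", call. = FALSE)

  grid <- phantom$grid
  V <- prod(grid)
  base <- as.vector(phantom$baseline)
  Y <- matrix(base, n, V, byrow = TRUE)

  # activation: sum of per-condition HRF regressors for each contrast's ROI
  catalogue <- localizer_contrasts()
  for (cname in names(effect_size)) {
    e <- effect_size[[cname]]
    if (e == 0) next
    conds <- if (!is.null(respond) && !is.null(respond[[cname]])) {
      respond[[cname]]
    } else if (cname %in% names(catalogue)) {
      w <- catalogue[[cname]]
      names(w)[w > 0]
    } else {
      unique(events$condition)
    }
    conds <- intersect(conds, unique(events$condition))
    if (!length(conds)) next
    x <- rowSums(vapply(conds, function(cc)
      condition_regressor(events, cc, n, TR, hrf), numeric(n)))
    idx <- which(as.vector(phantom$roi[[cname]]))
    Y[, idx] <- Y[, idx] * (1 + e * matrix(x, n, length(idx)))
  }

  with_seed(seed, {
    brain <- which(as.vector(phantom$brain_mask))
    tt <- (seq_len(n) - 1) * TR

    # slow drift: per-voxel polynomial with coefficients uniform in
    # [-amp, amp] * baseline on orthogonal poly columns scaled to max |1|
    if (profile$drift_amp > 0 && profile$drift_order >= 1L) {
      D <- stats::poly(tt, degree = profile$drift_order)
      D <- sweep(D, 2, apply(abs(D), 2, max), `/`)
      A <- matrix(stats::runif(profile$drift_order * length(brain), -1, 1) *
                    profile$drift_amp * rep(base[brain],
                                            each = profile$drift_order),
                  profile$drift_order, length(brain))
      Y[, brain] <- Y[, brain] + D %*% A
    }

    # shared physiological components: respiratory-like and cardiac-aliased
    # sinusoids plus one smooth random walk, all unit variance; loadings are
    # tissue-weighted (largest in WM/CSF) with mild voxelwise variation
    if (profile$n_physio > 0L) {
      freqs <- c(0.3, 1.05, NA)      # Hz; NA marks the random-walk component
      G <- matrix(0, n, profile$n_physio)
      for (k in seq_len(profile$n_physio)) {
        f <- freqs[((k - 1L) %% 3L) + 1L]
        g <- if (is.na(f)) {
          cumsum(stats::rnorm(n))
        } else {
          sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
        }
        g <- g - mean(g)
        s <- stats::sd(g)
        G[, k] <- if (s > 0) g / s else g
      }
      amp <- profile$physio_amp
      tiss <- amp[["gm"]] * as.vector(phantom$gm) +
        amp[["wm"]] * as.vector(phantom$wm) +
        amp[["csf"]] * as.vector(phantom$csf)
      L <- matrix(stats::runif(profile$n_physio * length(brain), 0.7, 1.3),
                  profile$n_physio, length(brain)) *
        rep(tiss[brain] * base[brain], each = profile$n_physio)
      Y[, brain] <- Y[, brain] + G %*% L
    }

    # AR(1) thermal noise, stationary marginal sd = thermal_sd * baseline
    if (profile$thermal_sd > 0) {
      burn <- 50L
      innov <- matrix(stats::rnorm((n + burn) * length(brain),
                                   sd = sqrt(1 - profile$rho^2)),
                      n + burn, length(brain))
      eps <- if (profile$rho > 0) {
        matrix(stats::filter(innov, profile$rho, method = "recursive"),
               n + burn, length(brain))
      } else innov
      eps <- eps[(burn + 1L):(burn + n), , drop = FALSE]
      Y[, brain] <- Y[, brain] +
        eps * matrix(profile$thermal_sd * base[brain], n, length(brain),
                     byrow = TRUE)
    }
    matrix_to_volume(Y, grid, TR, phantom$voxel_size,
                     mask = phantom$brain_mask)
  })
}
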