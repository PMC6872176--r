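#' Build a digital head phantom with tissue structure and reference ROIs
#'
#' The phantom is a spherical "head": a cerebrospinal-fluid (CSF) core
#' standing in for the ventricles, a white-matter (WM) shell around it, and a
#' grey-matter (GM) rind at the surface, with smooth transitions between
#' tissue classes. Each class reaches probability 1 in its interior so that
#' noise-ROI masks can be taken at probability 1, as anatomical CompCor
#' requires. One compact, non-overlapping reference ROI per contrast is placed
#' inside the GM rind; these play the role of the ground-truth activation
#' regions against which detection is scored.
#'
#' @param grid Integer vector of 3 voxel dimensions (each >= 8).
#' @param voxel_size Isotropic voxel size in mm.
#' @param contrast_names Character vector naming the contrasts; one ROI each.
#' @param seed Integer seed controlling ROI placement jitter.
#' @param roi_radius ROI sphere radius in voxels.
#' @return A list of class `phantom` with elements `grid`, `voxel_size`,
#'   `gm`, `wm`, `csf` (3D probability arrays), `baseline` (3D array, 100
#'   inside the brain), `brain_mask` (logical 3D array) and `roi` (named list
#'   of logical 3D arrays).
#' @export
#' @examples
#' ph <- generate_phantom(c(20, 20, 20), 2, c("video_minus_audio"), seed = 3)
#' sum(ph$roi$video_minus_audio)
generate_phantom <- function(grid = c(20L, 20L, 20L), voxel_size = 2,
                             contrast_names = sensorimotor_contrasts(),
                             seed = 1, roi_radius = 2) {
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 8L))
    stop("grid must have 3 dimensions of at least 8 voxels each", call. = FALSE)
  assert_scalar_num(voxel_size, "voxel_size", lower = 0, strict_lower = TRUE)
  if (length(contrast_names) < 1L)
    stop("at least one contrast name is required", call. = FALSE)
  if (anyDuplicated(contrast_names))
    stop("contrast names must be unique", call. = FALSE)

  centre <- (grid + 1) / 2
  rad <- min(grid) / 2 - 1          # brain radius in voxels
  ax <- lapply(1:3, function(i) seq_len(grid[i]) - centre[i])
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)) / rad

  ramp <- function(x) pmin(1, pmax(0, x))
  csf <- ramp((0.28 - r) / 0.08)
  wm  <- ramp((r - 0.25) / 0.08) * ramp((0.62 - r) / 0.08)
  gm  <- ramp((r - 0.58) / 0.08) * ramp((0.98 - r) / 0.06)
  tot <- csf + wm + gm
  over <- tot > 1
  if (any(over)) {              # keep per-voxel tissue probabilities <= 1
    csf[over] <- csf[over] / tot[over]
    wm[over] <- wm[over] / tot[over]
    gm[over] <- gm[over] / tot[over]
  }
  brain <- tot >= 0.05      # covers the whole >= 5% grey band
  baseline <- array(0, grid)
  baseline[brain] <- 100

  # ROIs: spheres centred on the GM rind at evenly spaced azimuths (plus a
  # seeded jitter), alternating slightly above/below the equatorial plane
  k <- length(contrast_names)
  roi <- with_seed(seed, {
    theta0 <- stats::runif(1, 0, 2 * pi)
    out <- vector("list", k)
    names(out) <- contrast_names
    for (i in seq_len(k)) {
      theta <- theta0 + 2 * pi * (i - 1) / k + stats::runif(1, -0.1, 0.1)
      phi <- (-1)^i * 0.35
      cen <- centre + 0.775 * rad *
        c(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
      d2 <- outer(outer((seq_len(grid[1]) - cen[1])^2,
                        (seq_len(grid[2]) - cen[2])^2, `+`),
                  (seq_len(grid[3]) - cen[3])^2, `+`)
      out[[i]] <- d2 <= roi_radius^2 & gm >= 0.05
    }
    out
  })
  counts <- vapply(roi, sum, 0L)
  if (any(counts == 0L))
    stop("grid too small to place ROI(s): ",
         paste(contrast_names[counts == 0L], collapse = ", "), call. = FALSE)
  pair_overlap <- if (k > 1L)
    Reduce(`+`, lapply(roi, function(m) m * 1L)) else roi[[1]] * 1L
  if (any(pair_overlap > 1L))
    stop("grid too small: ROIs overlap; enlarge the grid or shrink roi_radius",
         call. = FALSE)

  structure(list(grid = grid, voxel_size = voxel_size, gm = gm, wm = wm,
                 csf = csf, baseline = baseline, brain_mask = brain,
                 roi = roi),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s voxels @ %.3g mm, %d ROI(s): %s\n",
              paste(x$grid, collapse = "x"), x$voxel_size, length(x$roi),
              paste(names(x$roi), collapse = ", ")))
  invisible(x)
}

#' Define a noise profile for BOLD simulation
#'
#' A noise profile bundles the variance structure of a simulated acquisition:
#' AR(1)-correlated thermal noise, a small set of low-rank "physiological"
#' components with tissue-weighted spatial loadings (largest in WM/CSF), and
#' slow polynomial drift. Two presets mirror the qualitative contrast between
#' a thermal-noise-dominated multiband 2D acquisition (`"sms_like"`) and a
#' 3D acquisition with higher sensitivity to physiological noise
#' (`"epi3d_like"`): at comparable total variance the epi3d-like profile puts
#' a strictly larger fraction of it into the shared physiological components.
#'
#' All amplitudes are fractions of the baseline intensity, so 0.01 means a
#' fluctuation with standard deviation 1% of baseline.
#'
#' @param name `"sms_like"` or `"epi3d_like"` (presets), or any label when all
#'   numeric fields are supplied explicitly.
#' @param thermal_sd Marginal sd of the AR(1) thermal noise.
#' @param rho AR(1) coefficient of the thermal noise, in `[0, 1)`.
#' @param n_physio Number of physiological components (0 disables them).
#' @param physio_amp Named vector `c(gm=, wm=, csf=)` of per-tissue loading
#'   amplitudes for each physiological component.
#' @param drift_amp Amplitude of the per-voxel polynomial drift.
#' @param drift_order Polynomial drift order (default 2).
#' @return A list of class `noise_profile`.
#' @export
#' @examples
#' noise_profile("sms_like")
#' noise_profile("epi3d_like")$physio_amp
noise_profile <- function(name = c("sms_like", "epi3d_like"),
                          thermal_sd = NULL, rho = NULL, n_physio = NULL,
                          physio_amp = NULL, drift_amp = NULL,
                          drift_order = 2L) {
  name <- name[1L]
  presets <- list(
    sms_like = list(thermal_sd = 0.02, rho = 0.2, n_physio = 3L,
                    physio_amp = c(gm = 0.002, wm = 0.006, csf = 0.008),
                    drift_amp = 0.01),
    epi3d_like = list(thermal_sd = 0.012, rho = 0.3, n_physio = 3L,
                      physio_amp = c(gm = 0.01, wm = 0.02, csf = 0.03),
                      drift_amp = 0.01)
  )
  base <- presets[[name]]
  if (is.null(base)) {
    if (is.null(thermal_sd) || is.null(rho) || is.null(n_physio) ||
        is.null(physio_amp) || is.null(drift_amp))
      stop("unknown profile name '", name,
           "'; supply all numeric fields explicitly", call. = FALSE)
    base <- list()
  }
  p <- list(
    name = name,
    thermal_sd = if (is.null(thermal_sd)) base$thermal_sd else thermal_sd,
    rho = if (is.null(rho)) base$rho else rho,
    n_physio = as.integer(if (is.null(n_physio)) base$n_physio else n_physio),
    physio_amp = if (is.null(physio_amp)) base$physio_amp else physio_amp,
    drift_amp = if (is.null(drift_amp)) base$drift_amp else drift_amp,
    drift_order = as.integer(drift_order)
  )
  assert_scalar_num(p$thermal_sd, "thermal_sd", lower = 0)
  assert_scalar_num(p$rho, "rho", lower = 0, upper = 1 - 1e-12)
  if (p$n_physio < 0L) stop("n_physio must be >= 0", call. = FALSE)
  if (!all(c("gm", "wm", "csf") %in% names(p$physio_amp)))
    stop("physio_amp must name gm, wm and csf amplitudes", call. = FALSE)
  if (any(p$physio_amp < 0) || p$drift_amp < 0)
    stop("noise amplitudes must be >= 0", call. = FALSE)
  structure(p, class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf(
    "noise_profile '%s': thermal sd %.3g (rho %.2f), %d physio comps (gm %.3g, wm %.3g, csf %.3g), drift %.3g\n",
    x$name, x$thermal_sd, x$rho, x$n_physio, x$physio_amp[["gm"]],
    x$physio_amp[["wm"]], x$physio_amp[["csf"]], x$drift_amp))
  invisible(x)
}
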