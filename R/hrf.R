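#' Specify a canonical double-gamma hemodynamic response function
#'
#' Defaults follow the de-facto canonical parameterisation used by standard
#' fMRI analysis software: response peaking at 6 s, undershoot at 16 s, unit
#' dispersions, undershoot scaled by 1/6, kernel length 32 s, sampled on a
#' 0.1 s grid.
#'
#' @param step Sampling step in seconds for the kernel grid.
#' @param peak_delay Delay of the positive response peak (s).
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions.
#' @param ratio Undershoot-to-peak amplitude ratio.
#' @param length_out Kernel length in seconds.
#' @return A list of class `hrf_spec`.
#' @export
hrf_spec <- function(step = 0.1, peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     ratio = 1 / 6, length_out = 32) {
  vals <- c(step, peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, ratio, length_out)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all HRF parameters must be positive and finite", call. = FALSE)
  if (length_out < undershoot_delay)
    stop("kernel length must cover the undershoot delay", call. = FALSE)
  structure(list(step = step, peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, length_out = length_out),
            class = "hrf_spec")
}

#' Sample the canonical hemodynamic response function
#'
#' Difference of two gamma densities — a positive lobe minus a ratio-scaled
#' undershoot — sampled at the spec's step over its kernel length and
#' peak-normalised to a maximum of 1. The gamma shape parameters are
#' delay/dispersion, the scale parameters the dispersions.
#'
#' @param spec An [hrf_spec].
#' @return Numeric vector of kernel samples at times
#'   `seq(0, length_out, by = step)`, with the time grid in attribute `"time"`
#'   and the step in `"step"`.
#' @export
#' @examples
#' h <- canonical_hrf()
#' attr(h, "time")[which.max(h)]   # peak near 5 s
canonical_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  tt <- seq(0, spec$length_out, by = spec$step)
  h <- stats::dgamma(tt, shape = spec$peak_delay / spec$peak_dispersion,
                     scale = spec$peak_dispersion) -
    spec$ratio *
    stats::dgamma(tt, shape = spec$undershoot_delay / spec$undershoot_dispersion,
                  scale = spec$undershoot_dispersion)
  h <- h / max(h)
  attr(h, "time") <- tt
  attr(h, "step") <- spec$step
  h
}

#' Temporal derivative of the canonical HRF
#'
#' Finite-difference derivative of [canonical_hrf()] on the same grid,
#' included in the design to absorb small latency shifts of the response.
#' The first sample is `h[1]/step` so the cumulative sum telescopes back to
#' the kernel itself.
#'
#' @param spec An [hrf_spec].
#' @return Numeric vector the same length as `canonical_hrf(spec)`.
#' @export
hrf_derivative <- function(spec = hrf_spec()) {
  h <- canonical_hrf(spec)
  d <- c(h[1L], diff(h)) / spec$step
  attr(d, "time") <- attr(h, "time")
  attr(d, "step") <- spec$step
  d
}
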