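#' Discrete-cosine high-pass drift basis
#'
#' DCT-II columns for all frequencies below `1/cutoff`, excluding the
#' constant, following the column-count convention of standard fMRI analysis
#' software: `K = floor(2 * n_volumes * TR / cutoff)`. Columns are
#' orthonormal.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param TR Repetition time in seconds.
#' @param cutoff High-pass cut-off period in seconds (default 128 s); must
#'   exceed `2 * TR`.
#' @return An `n_volumes x K` matrix (possibly with 0 columns) with columns
#'   named `drift_1 ... drift_K`.
#' @export
#' @examples
#' ncol(dct_highpass_basis(267, 1.2, 128))   # 5
dct_highpass_basis <- function(n_volumes, TR, cutoff = 128) {
  assert_scalar_num(n_volumes, "n_volumes", lower = 2)
  assert_scalar_num(TR, "TR", lower = 0, strict_lower = TRUE)
  n <- as.integer(n_volumes)
  if (!is.infinite(cutoff)) assert_scalar_num(cutoff, "cutoff", lower = 0,
                                              strict_lower = TRUE)
  if (cutoff <= 2 * TR)
    stop("cutoff must exceed 2*TR; a shorter period would alias", call. = FALSE)
  K <- if (is.infinite(cutoff)) 0L else floor(2 * n * TR / cutoff)
  B <- matrix(0, n, K)
  tt <- seq_len(n)
  for (k in seq_len(K))
    B[, k] <- sqrt(2 / n) * cos(pi * (2 * tt - 1) * k / (2 * n))
  if (K > 0L) colnames(B) <- paste0("drift_", seq_len(K))
  B
}

# residual after projecting out an orthonormal drift basis (plus nothing else)
project_out_dct <- function(Y, B) {
  if (NCOL(B) == 0L) return(Y)
  Y - B %*% (t(B) %*% Y)
}

#' Temporal signal-to-noise ratio map
#'
#' Per voxel, the temporal mean of the raw series divided by the sample
#' standard deviation of the detrended series. Detrending projects out the
#' same discrete-cosine drift basis used by the GLM high-pass; with
#' `detrend_cutoff = NULL` the raw series is used. Voxels with zero temporal
#' standard deviation are undefined (`NA`).
#'
#' @param vol A [volume4d] with at least 3 volumes.
#' @param detrend_cutoff High-pass cut-off period in seconds, or `NULL` for
#'   no detrending; must exceed `2 * TR`.
#' @return A [stat_map] of kind `"tsnr"` on the volume's grid.
#' @export
compute_tsnr <- function(vol, detrend_cutoff = 128) {
  stopifnot(inherits(vol, "volume4d"))
  n <- dim(vol$data)[4]
  if (n < 3L) stop("tSNR needs at least 3 volumes", call. = FALSE)
  Y <- as_timeseries_matrix(vol)
  m <- colMeans(Y)
  R <- if (is.null(detrend_cutoff)) Y else
    project_out_dct(Y, dct_highpass_basis(n, vol$TR, detrend_cutoff))
  s <- sqrt(colSums(sweep(R, 2, colMeans(R))^2) / (n - 1))
  tsnr <- ifelse(s > 0, m / s, NA_real_)
  tsnr[tsnr < 0 & !is.na(tsnr)] <- 0   # negative-mean voxels clip to 0
  stat_map(array(tsnr, dim(vol$data)[1:3]), "tsnr",
           voxel_size = vol$voxel_size)
}

# zero-padded separable 1D Gaussian convolution matrix for one axis
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox == 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  w <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    keep <- j >= 1L & j <= n
    K[i, j[keep]] <- w[keep]
  }
  K
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, converted from mm to voxels using the isotropic voxel size.
#' Boundaries are zero-padded; `fwhm = 0` is the identity.
#'
#' @param x A [volume4d] or a 3D [stat_map].
#' @param fwhm Full width at half maximum in mm.
#' @return The same type as `x`, smoothed.
#' @export
gaussian_smooth <- function(x, fwhm) {
  assert_scalar_num(fwhm, "fwhm", lower = 0)
  if (inherits(x, "volume4d")) {
    vs <- x$voxel_size
    a <- x$data
  } else if (inherits(x, "stat_map")) {
    if (is.null(x$voxel_size))
      stop("stat_map has no voxel size; smoothing needs geometry",
           call. = FALSE)
    vs <- x$voxel_size
    a <- x$data
    if (!is.array(a) || length(dim(a)) != 3L)
      stop("only 3D stat_maps can be smoothed", call. = FALSE)
  } else stop("x must be a volume4d or stat_map", call. = FALSE)
  if (fwhm == 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  d <- dim(a)
  sm <- smooth_array(a, d, sigma)
  if (inherits(x, "volume4d")) {
    x$data <- sm
    x
  } else {
    stat_map(sm, x$kind, dof = x$dof, voxel_size = vs)
  }
}

# apply the same 1D kernel along each spatial axis of a 3D or 4D array
smooth_array <- function(a, d, sigma_vox) {
  nd <- length(d)
  spatial <- d[1:3]
  rest <- if (nd == 4L) d[4] else 1L
  m <- array(a, c(spatial, rest))
  for (ax in 1:3) {
    K <- gauss_conv_matrix(spatial[ax], sigma_vox)
    perm <- c(ax, setdiff(1:4, ax))
    mp <- aperm(m, perm)
    dp <- dim(mp)
    mp <- K %*% matrix(mp, dp[1])
    dim(mp) <- dp
    m <- aperm(mp, order(perm))
  }
  array(m, d)
}

#' Grey-matter band mask
#'
#' Voxels whose grey-matter probability is at least `threshold` (boundary
#' inclusive), the analysis band within which statistics are computed.
#'
#' @param gm_probability A [stat_map], 3D array or numeric vector of
#'   probabilities in `[0, 1]`.
#' @param threshold Inclusion threshold (default 0.05).
#' @return Logical array/vector of the same shape.
#' @export
#' @examples
#' grey_band_mask(c(0, 0.049, 0.05, 0.9))   # FALSE FALSE TRUE TRUE
grey_band_mask <- function(gm_probability, threshold = 0.05) {
  p <- if (inherits(gm_probability, "stat_map")) gm_probability$data
       else gm_probability
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  p >= threshold
}
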