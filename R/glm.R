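#' Anatomical CompCor nuisance regressors
#'
#' Extracts the top temporal principal components of the voxel series inside
#' a noise-tissue mask (white matter or CSF at tissue probability 1). Series
#' are first projected against the drift basis plus a constant, then
#' variance-normalised; the returned components are the leading left singular
#' vectors — zero-mean, mutually orthogonal, unit norm.
#'
#' @param vol A [volume4d] or a `t x V` series matrix.
#' @param mask Logical mask (3D array or vector over voxels/columns).
#' @param n_components Number of components (may be 0).
#' @param drift Optional drift matrix to project out (a constant is always
#'   projected).
#' @return A `t x n_components` matrix with columns `nuisance_1, ...`.
#' @export
compcor_regressors <- function(vol, mask, n_components, drift = NULL) {
  Y <- if (inherits(vol, "volume4d")) as_timeseries_matrix(vol) else
    as.matrix(vol)
  n <- nrow(Y)
  idx <- which(as.vector(mask))
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  n_components <- as.integer(n_components)
  if (n_components < 0L) stop("n_components must be >= 0", call. = FALSE)
  if (n_components == 0L)
    return(matrix(numeric(), n, 0L))
  if (n_components > min(n - 1L, length(idx)))
    stop("n_components exceeds min(n_volumes - 1, mask size)", call. = FALSE)
  M <- Y[, idx, drop = FALSE]
  B <- cbind(rep(1 / sqrt(n), n),
             if (!is.null(drift) && NCOL(drift) > 0) {
               q <- qr.Q(qr(sweep(as.matrix(drift), 2,
                                  colMeans(as.matrix(drift)))))
               q
             })
  scale0 <- sqrt(sum(M^2) / length(M))
  M <- M - B %*% (t(B) %*% M)
  s <- sqrt(colSums(M^2) / (n - 1))
  keep <- s > 1e-10 * max(scale0, 1e-300)
  if (!any(keep))
    stop("all mask series are constant after drift removal", call. = FALSE)
  M <- sweep(M[, keep, drop = FALSE], 2, s[keep], `/`)
  sv <- svd(M, nu = n_components, nv = 0)
  U <- sv$u
  # fix sign for reproducibility: largest-magnitude element positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  colnames(U) <- paste0("nuisance_", seq_len(ncol(U)))
  U
}

#' Pooled AR(1) coefficient of residual series
#'
#' Lag-1 autocorrelation pooled over voxels:
#' `rho = sum_v sum_t r_t r_(t+1) / sum_v sum_t r_t^2`, clipped to
#' `[0, 0.99]`.
#'
#' @param residuals `t x V` matrix of residual series (columns = voxels).
#' @param mask Optional logical vector selecting columns.
#' @return Scalar pooled AR(1) estimate.
#' @export
estimate_ar1 <- function(residuals, mask = NULL) {
  R <- as.matrix(residuals)
  if (nrow(R) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (!is.null(mask)) R <- R[, as.vector(mask), drop = FALSE]
  if (!ncol(R)) stop("mask is empty", call. = FALSE)
  denom <- sum(R^2)
  if (denom == 0) stop("residuals have zero variance", call. = FALSE)
  num <- sum(R[-nrow(R), , drop = FALSE] * R[-1L, , drop = FALSE])
  min(max(num / denom, 0), 0.99)
}

# pooled autocorrelation at lags 1..p
pooled_acf <- function(R, p) {
  n <- nrow(R)
  denom <- sum(R^2)
  vapply(seq_len(p), function(k)
    sum(R[seq_len(n - k), , drop = FALSE] *
          R[(k + 1L):n, , drop = FALSE]) / denom, 0)
}

# Residual autocorrelation bias correction.
#
# OLS residuals r = M y (M the residual-forming matrix) have attenuated
# autocorrelation because projection onto the design removes smooth,
# positively autocorrelated variance. For a true autocovariance sequence
# acvf, the expected pooled lag-k residual correlation is
#   g_k(acvf) = tr(B_k M V M) / tr(M V M),
# with V = toeplitz(acvf) and B_k the symmetric lag-k averaging matrix.
# predicted_resid_acf computes g_{1..p}; fit_glm inverts it so whitening
# uses an (approximately) unbiased autocorrelation of the noise itself.
predicted_resid_acf <- function(Q, acvf, p) {
  n <- length(acvf)
  V <- stats::toeplitz(acvf)
  A <- crossprod(Q, V)                        # k x n
  MVM <- V - Q %*% A - t(A) %*% t(Q) + Q %*% (A %*% Q) %*% t(Q)
  denom <- sum(diag(MVM))
  vapply(seq_len(p), function(k)
    sum(MVM[cbind(seq_len(n - k), (k + 1L):n)]) / denom, 0)
}

# invert the AR(1) residual-bias map: find rho with g_1(rho) = rho_obs
debias_ar1 <- function(rho_obs, Q, n) {
  g <- function(rho) predicted_resid_acf(Q, rho^(0:(n - 1L)), 1L) - rho_obs
  if (g(0) >= 0) return(0)
  if (g(0.99) <= 0) return(0.99)
  stats::uniroot(g, c(0, 0.99), tol = 1e-4)$root
}

# fixed-point inversion of the bias map for AR(p): adjust the target acf
# until the predicted residual acf matches the observed one
debias_arp <- function(acf_obs, Q, n, p, iters = 12L) {
  acf_est <- acf_obs
  phi <- NULL
  for (it in seq_len(iters)) {
    phi <- solve(stats::toeplitz(c(1, acf_est[seq_len(p - 1L)])),
                 acf_est[seq_len(p)])
    while (any(Mod(polyroot(c(1, -phi))) <= 1.001)) phi <- phi * 0.95
    acvf <- as.numeric(stats::ARMAacf(ar = phi, lag.max = n - 1L))
    pred <- predicted_resid_acf(Q, acvf, p)
    acf_est <- pmin(0.995, pmax(-0.995, acf_est + (acf_obs - pred)))
  }
  as.numeric(phi)
}

# whitening transform W (n x n, lower triangular action) for an AR process:
# for AR(1) the banded analytic form; for AR(p) the inverse Cholesky of the
# stationary autocorrelation matrix
ar_whitening_matrix <- function(n, phi) {
  if (length(phi) == 1L) {
    rho <- phi
    W <- diag(n)
    if (rho != 0) {
      W[1, 1] <- sqrt(1 - rho^2)
      for (i in 2:n) W[i, i - 1L] <- -rho
    }
    return(W)
  }
  ac <- stats::ARMAacf(ar = phi, lag.max = n - 1L)
  Rm <- stats::toeplitz(as.numeric(ac))
  # W = L^{-1} with R = L L' ; then cov(W r) = I (up to innovation scale)
  L <- t(chol(Rm))
  forwardsolve(L, diag(n))
}

#' Fit the mass-univariate GLM with optional prewhitening
#'
#' Per-voxel least squares on a shared design, with three whitening models:
#' `"ols"` (none), `"ar1"` (two-pass: OLS residuals, pooled lag-1
#' autocorrelation, AR(1) whitening transform applied to data and design,
#' then OLS), and `"extended"` (same two-pass scheme with a pooled
#' autoregressive model of order `ar_order`, default 3, fitted to the
#' residual autocorrelation by Yule-Walker — a higher-order stand-in for
#' multi-component noise models). Because OLS residuals understate the noise
#' autocorrelation (projection onto smooth design columns removes
#' autocorrelated variance), the pooled estimates are bias-corrected by
#' inverting the expected residual autocorrelation as a function of the true
#' one (a trace/method-of-moments correction) before the whitening transform
#' is built. Degrees of freedom are `n_volumes - rank(X)`.
#'
#' @param vol A [volume4d] or a `t x V` data matrix.
#' @param X A [design_matrix()] with `n_volumes` rows.
#' @param whitening `"ols"`, `"ar1"` or `"extended"`.
#' @param ar_order Autoregressive order for `"extended"`.
#' @param mask Optional logical mask: voxels used to pool the autocorrelation
#'   estimate (defaults to the volume's brain mask, else all voxels).
#' @param rho Optional fixed AR(1) coefficient, bypassing estimation
#'   (`"ar1"` only).
#' @return A list of class `glm_fit` with `beta` (p x V), `sigma2` (V),
#'   `dof`, `whitening`, `rho` / `ar_coef`, `xtx_inv` (of the whitened
#'   design), plus the grid geometry when `vol` was a [volume4d].
#' @export
fit_glm <- function(vol, X, whitening = c("ols", "ar1", "extended"),
                    ar_order = 3L, mask = NULL, rho = NULL) {
  whitening <- match.arg(whitening)
  stopifnot(inherits(X, "design_matrix"))
  grid <- NULL; voxel_size <- NULL
  if (inherits(vol, "volume4d")) {
    grid <- dim(vol$data)[1:3]
    voxel_size <- vol$voxel_size
    if (is.null(mask) && !is.null(vol$mask)) mask <- as.vector(vol$mask)
    Y <- as_timeseries_matrix(vol)
  } else {
    Y <- as.matrix(vol)
  }
  n <- nrow(Y)
  p <- ncol(X)
  if (nrow(X) != n)
    stop("design rows must equal the number of volumes", call. = FALSE)
  if (n <= p)
    stop("more regressors than time points leaves no residual dof",
         call. = FALSE)
  Xm <- unclass(X)

  ols_fit <- function(Yw, Xw) {
    qx <- qr(Xw)
    beta <- qr.coef(qx, Yw)
    res <- Yw - Xw %*% beta
    list(beta = beta, res = res, qx = qx)
  }

  f0 <- ols_fit(Y, Xm)
  dof <- n - qr(Xm)$rank
  rho_hat <- NULL; ar_coef <- NULL
  if (whitening == "ols") {
    fit <- f0
    W <- NULL
    Xw <- Xm
  } else if (whitening == "ar1") {
    rho_hat <- if (!is.null(rho)) {
      assert_scalar_num(rho, "rho", lower = 0, upper = 0.99)
      rho
    } else {
      Rm <- if (is.null(mask)) f0$res else
        f0$res[, as.vector(mask), drop = FALSE]
      if (sum(Rm^2) == 0) stop("residuals have zero variance", call. = FALSE)
      obs <- pooled_acf(Rm, 1L)        # unclipped observed lag-1
      min(max(debias_ar1(obs, qr.Q(f0$qx), n), 0), 0.99)
    }
    W <- ar_whitening_matrix(n, rho_hat)
    Xw <- W %*% Xm
    fit <- ols_fit(W %*% Y, Xw)
  } else {
    Rm <- if (is.null(mask)) f0$res else f0$res[, as.vector(mask), drop = FALSE]
    if (sum(Rm^2) == 0) stop("residuals have zero variance", call. = FALSE)
    r <- pooled_acf(Rm, ar_order)
    ar_coef <- debias_arp(r, qr.Q(f0$qx), n, ar_order)
    W <- ar_whitening_matrix(n, ar_coef)
    Xw <- W %*% Xm
    fit <- ols_fit(W %*% Y, Xw)
  }
  sigma2 <- colSums(fit$res^2) / dof
  xtx_inv <- chol2inv(qr.R(fit$qx))
  structure(list(beta = fit$beta, sigma2 = sigma2, dof = dof,
                 whitening = whitening, rho = rho_hat, ar_coef = ar_coef,
                 xtx_inv = xtx_inv, labels = attr(X, "labels"),
                 grid = grid, voxel_size = voxel_size),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit: %d regressors x %d voxels, whitening %s%s, dof %d\n",
              nrow(x$beta), ncol(x$beta), x$whitening,
              if (!is.null(x$rho)) sprintf(" (rho %.3f)", x$rho) else "",
              x$dof))
  invisible(x)
}

#' Contrast t-statistic map
#'
#' Per voxel, `t = c'beta / sqrt(sigma2 * c' (Xw' Xw)^-1 c)` where `Xw` is
#' the design under the whitening transform used at fit time. Voxels with a
#' zero denominator are undefined (`NA`).
#'
#' @param fit A [fit_glm()] result.
#' @param X The [design_matrix()] used for the fit (for label checking).
#' @param contrast A [contrast_spec()], or a contrast name resolved against
#'   the design.
#' @return A [stat_map] of kind `"t"` (3D when the fit carries a grid, else a
#'   vector-backed map).
#' @export
contrast_tmap <- function(fit, X, contrast) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.character(contrast)) contrast <- contrast_spec(X, contrast)
  stopifnot(inherits(contrast, "contrast_spec"))
  w <- contrast$weights
  if (length(w) != nrow(fit$beta))
    stop("contrast length must equal the number of design columns",
         call. = FALSE)
  eff <- drop(crossprod(w, fit$beta))
  se2 <- fit$sigma2 * drop(t(w) %*% fit$xtx_inv %*% w)
  tval <- ifelse(se2 > 0, eff / sqrt(se2), NA_real_)
  dat <- if (!is.null(fit$grid)) array(tval, fit$grid) else tval
  stat_map(dat, "t", dof = fit$dof, voxel_size = fit$voxel_size)
}
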