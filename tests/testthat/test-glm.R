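test_that("CompCor recovers a planted two-component physiological subspace", {
  set.seed(10)
  n <- 200
  tt <- seq_len(n)
  g1 <- sin(2 * pi * 5 * tt / n); g1 <- g1 / sd(g1)
  g2 <- cos(2 * pi * 11 * tt / n); g2 <- g2 / sd(g2)
  L <- matrix(runif(2 * 60, 0.5, 1.5), 2, 60)
  Y <- cbind(g1, g2) %*% L + matrix(rnorm(n * 60, sd = 0.01), n)
  U <- compcor_regressors(Y, rep(TRUE, 60), 2)
  cc <- cancor(U, cbind(g1, g2))$cor
  expect_true(all(cc > 0.99))
  # SVD components are zero-mean and mutually orthogonal
  expect_lt(max(abs(colMeans(U))), 1e-10)
  expect_lt(abs(crossprod(U[, 1], U[, 2])), 1e-10)
})

test_that("CompCor validates sizes and degenerate masks", {
  Y <- matrix(rnorm(50 * 5), 50)
  expect_equal(ncol(compcor_regressors(Y, rep(TRUE, 5), 0)), 0L)
  expect_error(compcor_regressors(Y, rep(TRUE, 5), 10), "exceeds")
  expect_error(compcor_regressors(Y, rep(FALSE, 5), 2), "empty")
  expect_error(compcor_regressors(matrix(3, 50, 4), rep(TRUE, 4), 2),
               "constant")
})

test_that("pooled AR(1) estimation is calibrated and clipped", {
  set.seed(20)
  white <- matrix(rnorm(500 * 200), 500)
  expect_lt(abs(estimate_ar1(white)), 0.05)
  ar <- matrix(stats::filter(matrix(rnorm(500 * 200, sd = sqrt(1 - 0.25)),
                                    500), 0.5, method = "recursive"),
               500, 200)
  expect_gt(estimate_ar1(ar), 0.45)
  expect_lt(estimate_ar1(ar), 0.55)
  neg <- matrix(stats::filter(matrix(rnorm(500 * 50), 500), -0.3,
                              method = "recursive"), 500, 50)
  expect_equal(estimate_ar1(neg), 0)
  expect_error(estimate_ar1(matrix(0, 10, 3)), "zero variance")
})

test_that("noiseless data are interpolated exactly", {
  ev <- generate_paradigm(120, 1, min_gap = 2, seed = 3)
  X <- build_design_matrix(ev, 100, 1.2,
                           drift = dct_highpass_basis(100, 1.2, 64))
  b <- runif(ncol(X), -1, 1)
  Y <- cbind(unclass(X) %*% b, unclass(X) %*% (2 * b))
  fit <- fit_glm(Y, X, "ols")
  expect_lt(max(abs(fit$beta[, 1] - b)), 1e-10)
  expect_lt(max(abs(fit$beta[, 2] - 2 * b)), 1e-10)
  expect_lt(max(fit$sigma2), 1e-20)
})

test_that("AR(1) whitening at rho 0 reproduces OLS exactly", {
  set.seed(30)
  ev <- generate_paradigm(120, 1, min_gap = 2, seed = 3)
  X <- build_design_matrix(ev, 100, 1.2)
  Y <- matrix(rnorm(100 * 20), 100)
  f_ols <- fit_glm(Y, X, "ols")
  f_ar <- fit_glm(Y, X, "ar1", rho = 0)
  expect_equal(f_ar$beta, f_ols$beta, tolerance = 1e-10)
  cs <- contrast_spec(X, "vs", weights = c(visual_sentence = 1))
  t_ols <- contrast_tmap(f_ols, X, cs)
  t_ar <- contrast_tmap(f_ar, X, cs)
  expect_equal(t_ar$data, t_ols$data, tolerance = 1e-6)
})

test_that("t statistics match a brute-force normal-equations solver on a printed fixture", {
  X_raw <- matrix(c(
    0.0, 0.2, 0.9, 1.0, 0.6, 0.1, 0.0, 0.0, 0.3, 0.8, 0.7, 0.2,
    0.5, -0.3, 0.1, 0.4, -0.2, 0.6, -0.5, 0.2, 0.0, -0.4, 0.3, 0.1,
    1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 12, 3)
  Y <- matrix(c(
    10.2, 10.5, 11.9, 12.4, 11.1, 10.0, 9.8, 10.1, 10.7, 12.0, 11.6, 10.3,
    5.1, 4.8, 5.6, 5.9, 5.2, 5.0, 4.7, 5.1, 5.3, 5.8, 5.5, 5.0), 12, 2)
  X <- design_matrix(X_raw, c("task", "mod", "constant"), TR = 1)
  fit <- fit_glm(Y, X, "ols")
  tm <- contrast_tmap(fit, X, contrast_spec(X, "task", weights = c(task = 1)))
  # independent brute-force solver
  for (v in 1:2) {
    b <- solve(t(X_raw) %*% X_raw) %*% t(X_raw) %*% Y[, v]
    r <- Y[, v] - X_raw %*% b
    s2 <- sum(r^2) / (12 - 3)
    cvec <- c(1, 0, 0)
    t_ref <- drop(t(cvec) %*% b) /
      sqrt(s2 * drop(t(cvec) %*% solve(t(X_raw) %*% X_raw) %*% cvec))
    expect_equal(tm$data[v], t_ref, tolerance = 1e-6)
  }
})

test_that("whitened OLS equals GLS with the matching covariance", {
  set.seed(40)
  n <- 40
  X_raw <- cbind(rnorm(n), 1)
  X <- design_matrix(X_raw, c("x", "constant"), TR = 1)
  rho <- 0.6
  V <- toeplitz(rho^(0:(n - 1)))
  Y <- matrix(rnorm(n * 3), n)
  fit <- fit_glm(Y, X, "ar1", rho = rho)
  Vi <- solve(V)
  b_gls <- solve(t(X_raw) %*% Vi %*% X_raw) %*% t(X_raw) %*% Vi %*% Y
  expect_equal(unname(fit$beta), unname(b_gls), tolerance = 1e-8)
})

test_that("t statistics are invariant to rescaling a column with its weight", {
  set.seed(50)
  n <- 60
  X1 <- design_matrix(cbind(rnorm(n), 1), c("x", "constant"), TR = 1)
  X2 <- design_matrix(cbind(10 * unclass(X1)[, 1], 1), c("x", "constant"),
                      TR = 1)
  Y <- matrix(rnorm(n * 4), n)
  t1 <- contrast_tmap(fit_glm(Y, X1, "ols"), X1,
                      contrast_spec(X1, "c", weights = c(x = 1)))
  t2 <- contrast_tmap(fit_glm(Y, X2, "ols"), X2,
                      contrast_spec(X2, "c", weights = c(x = 0.1)))
  expect_equal(t1$data, t2$data, tolerance = 1e-10)
})

test_that("AR(1) prewhitening leaves whitened residuals near-white", {
  ph <- small_phantom()
  ev <- generate_paradigm(320, 3, min_gap = 2, seed = 1)
  vol <- simulate_bold(ph, ev, c(video_minus_audio = 0),
                       thermal_profile(sd = 0.01, rho = 0.6), 267, 1.2,
                       seed = 6)
  X <- build_design_matrix(ev, 267, 1.2,
                           drift = dct_highpass_basis(267, 1.2, 128))
  fit <- fit_glm(vol, X, "ar1")
  W <- fmriseqbench:::ar_whitening_matrix(267, fit$rho)
  Y <- as_timeseries_matrix(vol)[, as.vector(ph$brain_mask)]
  Xw <- W %*% unclass(X)
  res <- W %*% Y - Xw %*% solve(crossprod(Xw), crossprod(Xw, W %*% Y))
  expect_lt(abs(estimate_ar1(res)), 0.05)
  expect_gt(fit$rho, 0.45)
})

test_that("task contrasts hold their nominal two-sided size on white noise", {
  set.seed(70)
  ev <- generate_paradigm(320, 3, min_gap = 2, seed = 70)
  X <- build_design_matrix(ev, 267, 1.2,
                           drift = dct_highpass_basis(267, 1.2, 128))
  Y <- matrix(rnorm(267 * 500), 267)
  fit <- fit_glm(Y, X, "ols")
  tm <- contrast_tmap(fit, X, "audio_minus_video")
  crit <- qt(0.975, fit$dof)
  frac <- mean(abs(tm$data) > crit)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("mean-signal t map is strongly positive across the brain", {
  ph <- small_phantom()
  ev <- generate_paradigm(120, 1, min_gap = 2, seed = 2)
  vol <- simulate_bold(ph, ev, c(video_minus_audio = 0),
                       thermal_profile(sd = 0.01, rho = 0), 100, 1.2,
                       seed = 7)
  X <- build_design_matrix(ev, 100, 1.2)
  fit <- fit_glm(vol, X, "ols")
  tm <- contrast_tmap(fit, X, "mean_signal")
  expect_true(all(tm$data[ph$brain_mask] > 0))
})
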