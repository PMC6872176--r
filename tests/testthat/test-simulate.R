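test_that("noise-free null simulation is constant at baseline", {
  ph <- small_phantom()
  ev <- generate_paradigm(60, 1, min_gap = 2, seed = 1)
  vol <- simulate_bold(ph, ev, c(video_minus_audio = 0), silent_profile(),
                       60, 1.2, seed = 1)
  Y <- as_timeseries_matrix(vol)
  expect_equal(apply(Y, 2, max), apply(Y, 2, min))
  expect_equal(Y[1, ], as.vector(ph$baseline))
})

test_that("noiseless activation is recovered exactly by least squares", {
  ph <- small_phantom()
  ev <- generate_paradigm(320, 3, min_gap = 2, seed = 1)
  vol <- simulate_bold(ph, ev, c(video_minus_audio = 0.02), silent_profile(),
                       267, 1.2, seed = 1)
  X <- build_design_matrix(ev, 267, 1.2)
  Y <- as_timeseries_matrix(vol)
  # closed-form least-squares oracle via the normal equations
  beta <- solve(crossprod(X), crossprod(X, Y))
  cw <- contrast_spec(X, "video_minus_audio")$weights
  eff <- drop(cw %*% beta)
  roi <- as.vector(ph$roi$video_minus_audio)
  truth <- 100 * 0.02
  expect_lt(max(abs(eff[roi] - truth) / truth), 1e-6)
  brain <- as.vector(ph$brain_mask)
  expect_equal(max(abs(eff[brain & !roi])), 0)
})

test_that("the noise-free forward model is linear in effect size", {
  ph <- small_phantom()
  ev <- generate_paradigm(120, 1, min_gap = 2, seed = 2)
  v1 <- simulate_bold(ph, ev, c(video_minus_audio = 0.01), silent_profile(),
                      100, 1.2, seed = 1)
  v2 <- simulate_bold(ph, ev, c(video_minus_audio = 0.02), silent_profile(),
                      100, 1.2, seed = 1)
  a1 <- as_timeseries_matrix(v1) - 100
  a2 <- as_timeseries_matrix(v2) - 100
  roi <- as.vector(ph$roi$video_minus_audio)
  expect_equal(a2[, roi], 2 * a1[, roi], tolerance = 1e-12)
})

test_that("generated thermal noise has the requested lag-1 autocorrelation", {
  ph <- generate_phantom(c(8, 8, 8), 2, "video_minus_audio", seed = 1,
                         roi_radius = 1)
  ev <- event_table(1, 1, "visual_sentence")
  vol <- simulate_bold(ph, ev, c(video_minus_audio = 0),
                       thermal_profile(sd = 0.01, rho = 0.5),
                       6000, 1.2, seed = 4)
  voxel <- which(as.vector(ph$brain_mask))[1]
  y <- as_timeseries_matrix(vol)[, voxel]
  r1 <- cor(y[-1], y[-length(y)])
  expect_lt(abs(r1 - 0.5), 0.05)
})

test_that("null tSNR converges to baseline over total noise sd", {
  ph <- generate_phantom(c(8, 8, 8), 2, "video_minus_audio", seed = 1,
                         roi_radius = 1)
  ev <- event_table(1, 1, "visual_sentence")
  vol <- simulate_bold(ph, ev, c(video_minus_audio = 0),
                       thermal_profile(sd = 0.02, rho = 0),
                       1200, 1.2, seed = 5)
  tsnr <- compute_tsnr(vol, detrend_cutoff = NULL)
  expected <- 100 / 2
  got <- mean(tsnr$data[ph$brain_mask], na.rm = TRUE)
  expect_lt(abs(got - expected) / expected, 0.05)
})

test_that("the 3D-like profile carries a larger physiological variance fraction", {
  ph <- small_phantom()
  ev <- generate_paradigm(120, 1, min_gap = 2, seed = 2)
  frac_physio <- function(profile) {
    full <- simulate_bold(ph, ev, c(video_minus_audio = 0), profile,
                          100, 1.2, seed = 9)
    no_physio <- noise_profile(profile$name, thermal_sd = profile$thermal_sd,
                               rho = profile$rho, n_physio = 0,
                               physio_amp = profile$physio_amp,
                               drift_amp = profile$drift_amp)
    part <- simulate_bold(ph, ev, c(video_minus_audio = 0), no_physio,
                          100, 1.2, seed = 9)
    vf <- mean(apply(as_timeseries_matrix(full)[, ph$brain_mask], 2, var))
    vp <- mean(apply(as_timeseries_matrix(part)[, ph$brain_mask], 2, var))
    (vf - vp) / vf
  }
  expect_gt(frac_physio(noise_profile("epi3d_like")),
            frac_physio(noise_profile("sms_like")))
})

test_that("simulation is deterministic per seed and validates inputs", {
  ph <- small_phantom()
  ev <- generate_paradigm(60, 1, min_gap = 2, seed = 1)
  a <- simulate_bold(ph, ev, c(video_minus_audio = 0.01),
                     noise_profile("sms_like"), 60, 1.2, seed = 11)
  b <- simulate_bold(ph, ev, c(video_minus_audio = 0.01),
                     noise_profile("sms_like"), 60, 1.2, seed = 11)
  expect_identical(a$data, b$data)
  expect_error(simulate_bold(ph, ev, c(no_such_roi = 0.01),
                             noise_profile("sms_like"), 60, 1.2, seed = 1),
               "without a phantom ROI")
  expect_error(simulate_bold(ph, ev, c(video_minus_audio = 0.01),
                             noise_profile("sms_like"), 20, 1.2, seed = 1),
               "beyond the run")
})
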