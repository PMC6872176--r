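# shared fixtures, built in code at test time

# a noise profile with every stochastic component switched off
silent_profile <- function() {
  noise_profile("silent", thermal_sd = 0, rho = 0, n_physio = 0,
                physio_amp = c(gm = 0, wm = 0, csf = 0), drift_amp = 0)
}

# thermal-only AR(1) profile
thermal_profile <- function(sd = 0.01, rho = 0) {
  noise_profile("thermal", thermal_sd = sd, rho = rho, n_physio = 0,
                physio_amp = c(gm = 0, wm = 0, csf = 0), drift_amp = 0)
}

small_phantom <- function(contrasts = "video_minus_audio", grid = 14L,
                          seed = 3, roi_radius = 2) {
  generate_phantom(rep(grid, 3), 2, contrasts, seed = seed,
                   roi_radius = roi_radius)
}

# detection point without running sens_spec
det_point <- function(sens, spec, n_roi = 100, n_out = 1000, alpha = 0.001) {
  structure(list(alpha = alpha, sensitivity = sens, specificity = spec,
                 tp = round(sens * n_roi), fp = round((1 - spec) * n_out),
                 n_roi = n_roi, n_out = n_out),
            class = "detection_point")
}

# evaluate with a local RNG seed without touching the session stream
with_seed_test <- function(seed, code) withr::with_seed(seed, code)

# independent normal quantile by numerical inversion of the integrated density
z_oracle <- function(prob) {
  vapply(prob, function(pr)
    uniroot(function(z)
      integrate(dnorm, -Inf, z, rel.tol = 1e-12)$value - pr,
      c(-8, 8), tol = 1e-10)$root, 0)
}
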