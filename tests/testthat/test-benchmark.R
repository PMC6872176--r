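test_that("p-maps follow the t distribution's tail and propagate NA", {
  expect_equal(pmap_from_tmap(stat_map(0, "t", dof = 10))$data, 0.5)
  # oracle: numerical integration of the t(10) density
  p_ref <- integrate(function(x) dt(x, 10), 2, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(pmap_from_tmap(stat_map(2, "t", dof = 10))$data - p_ref),
            1e-3)
  tv <- c(-1, 0, 1, 2, NA)
  p <- pmap_from_tmap(stat_map(tv, "t", dof = 7))$data
  expect_true(is.na(p[5]))
  expect_true(all(diff(p[1:4]) < 0))
  p2 <- pmap_from_tmap(stat_map(c(-2, 2), "t", dof = 7), sided = "two")$data
  expect_equal(p2[1], p2[2])
})

test_that("sensitivity and specificity count activated voxels correctly", {
  p <- c(1e-4, 1e-4, 1e-4, 0.9, 1e-4, 0.9, 0.9, 0.9, 0.9, 0.9)
  roi <- c(rep(TRUE, 4), rep(FALSE, 6))
  msk <- rep(TRUE, 10)
  pt <- sens_spec(p, roi, msk, 0.001)
  expect_equal(pt$sensitivity, 0.75)
  expect_equal(pt$specificity, 5 / 6)
  expect_equal(sens_spec(p, roi, msk, 0)$sensitivity, 0)     # strict <
  expect_equal(sens_spec(p, roi, msk, 0)$specificity, 1)
  expect_equal(sens_spec(p, roi, msk, 1)$sensitivity, 1)
  expect_equal(sens_spec(p, roi, msk, 1)$specificity, 0)
  expect_error(sens_spec(p, rep(FALSE, 10), msk, 0.1), "empty")
  expect_error(sens_spec(p, msk, msk, 0.1), "empty")
})

test_that("ROC endpoints: perfect separation gives AUC 1, anchors alone give 0.5", {
  p <- c(rep(1e-6, 50), rep(0.6, 450))
  roi <- c(rep(TRUE, 50), rep(FALSE, 450))
  roc <- roc_curve(p, roi, rep(TRUE, 500))
  expect_equal(roc$auc, 1)
  # a grid whose points all coincide with (0,0) leaves only the anchors
  p2 <- rep(0.9, 100)
  roi2 <- c(rep(TRUE, 10), rep(FALSE, 90))
  roc2 <- roc_curve(p2, roi2, rep(TRUE, 100))
  expect_true(all(roc2$points$sensitivity == 0))
  expect_equal(roc2$auc, 0.5)
})

test_that("ROC is monotone in the threshold exactly as the counts imply", {
  set.seed(60)
  p <- runif(2000)
  roi <- seq_len(2000) <= 300
  roc <- roc_curve(p, roi, rep(TRUE, 2000))
  expect_true(all(diff(roc$points$sensitivity) >= 0))
  expect_true(all(diff(roc$points$specificity) <= 0))
  expect_equal(roc$points$sensitivity, roc$points$tp / roc$n_roi)
  expect_equal(roc$points$specificity, 1 - roc$points$fp / roc$n_out)
})

test_that("AUC equals the brute-force Mann-Whitney statistic on small instances", {
  set.seed(61)
  for (rep_i in 1:3) {
    n_roi <- sample(5:40, 1)
    n_out <- sample(20:150, 1)
    # p-values in (0, 0.5] so every distinct value can sit on the grid
    p_roi <- runif(n_roi, 1e-4, 0.5) * rbeta(n_roi, 1, 3)
    p_out <- runif(n_out, 1e-4, 0.5)
    p_roi[1:2] <- p_out[1:2]     # force ties across groups
    p <- c(p_roi, p_out)
    roi <- c(rep(TRUE, n_roi), rep(FALSE, n_out))
    grid <- sort(unique(pmin(0.5, pmax(1e-12, p))))
    roc <- roc_curve(p, roi, rep(TRUE, n_roi + n_out), alpha_grid = grid)
    # brute-force pairwise oracle: ROI voxels should have smaller p
    mw <- mean(outer(p_roi, p_out, function(a, b)
      (a < b) + 0.5 * (a == b)))
    expect_equal(roc$auc, mw, tolerance = 1e-12)
  }
})

test_that("d-prime matches the inverse-normal oracle and handles clipping", {
  expect_equal(dprime(det_point(0.5, 0.5))$dprime, 0)
  dp <- dprime(det_point(0.8413447, 0.8413447))$dprime
  expect_lt(abs(dp - 2), 1e-3)
  z <- z_oracle(c(0.8413447, 1 - 0.8413447))
  expect_lt(abs(dp - (z[1] - z[2])), 1e-6)
  expect_error(dprime(det_point(1, 0.9)), "clip_counts")
  clipped <- dprime(det_point(1, 0.9, n_roi = 1000), clip_counts = TRUE)
  expect_true(clipped$clipped)
  expect_equal(clipped$dprime,
               qnorm(1 - 1 / 2000) - qnorm(0.1), tolerance = 1e-12)
})

test_that("d-prime is threshold-independent for Gaussian equal-variance scores", {
  set.seed(62)
  n_roi <- 20000; n_out <- 80000
  scores <- c(rnorm(n_roi, mean = 1.5), rnorm(n_out, 0))
  roi <- c(rep(TRUE, n_roi), rep(FALSE, n_out))
  p <- pmap_from_tmap(stat_map(scores, "t", dof = 1e6))$data
  dps <- vapply(c(0.01, 0.05, 0.2), function(a)
    dprime(sens_spec(p, roi, rep(TRUE, n_roi + n_out), a))$dprime, 0)
  expect_lt(max(abs(dps - 1.5)), 0.05)
})

test_that("aggregation reproduces its cells and is symmetric in subjects", {
  set.seed(63)
  mk_cell <- function(subject, contrast, shift) {
    p <- c(runif(40) * 10^(-shift), runif(160))
    roi <- c(rep(TRUE, 40), rep(FALSE, 160))
    pm <- pmin(1, p)
    roc <- roc_curve(pm, roi, rep(TRUE, 200))
    dp <- dprime(sens_spec(pm, roi, rep(TRUE, 200), 0.001),
                 clip_counts = TRUE)
    list(subject = subject, contrast = contrast, roc = roc, dprime = dp)
  }
  single <- mk_cell(1, "a", 2)
  agg1 <- aggregate_benchmark(list(single))
  expect_equal(agg1$auc_mean, single$roc$auc)
  expect_equal(agg1$dprime_mean, single$dprime$dprime)

  cells <- list(mk_cell(1, "a", 3), mk_cell(1, "b", 2),
                mk_cell(2, "a", 1), mk_cell(2, "b", 2))
  agg <- aggregate_benchmark(cells)
  expect_equal(agg$auc_mean, mean(agg$per_subject$auc))
  agg_rev <- aggregate_benchmark(rev(cells))
  expect_equal(sort(agg_rev$per_subject$auc), sort(agg$per_subject$auc))
  expect_equal(agg_rev$auc_mean, agg$auc_mean)
  expect_equal(agg_rev$dprime_mean, agg$dprime_mean)
})

test_that("aggregate summaries are recomputable from the stored per-subject values", {
  set.seed(64)
  mk_cell <- function(subject, shift) {
    p <- pmin(1, c(runif(40) * 10^(-shift), runif(160)))
    roi <- c(rep(TRUE, 40), rep(FALSE, 160))
    list(subject = subject, contrast = "a",
         roc = roc_curve(p, roi, rep(TRUE, 200)),
         dprime = dprime(sens_spec(p, roi, rep(TRUE, 200), 0.001),
                         clip_counts = TRUE))
  }
  agg <- aggregate_benchmark(list(mk_cell(1, 3), mk_cell(2, 0.5)))
  expect_equal(agg$auc_mean, mean(agg$per_subject$auc))
  expect_equal(agg$auc_sd, sd(agg$per_subject$auc))
  expect_equal(agg$dprime_mean, mean(agg$per_subject$dprime))
  # two-point mean/sd arithmetic on the subject AUCs
  a <- agg$per_subject$auc
  expect_equal(agg$auc_sd, abs(a[1] - a[2]) / sqrt(2), tolerance = 1e-12)
})
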