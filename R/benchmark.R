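#' Convert a t-map to a p-map
#'
#' One-sided (default) upper-tail probabilities of the t distribution with
#' the map's degrees of freedom, or two-sided probabilities of |t|.
#' Undefined t voxels propagate as undefined p.
#'
#' @param t A [stat_map] of kind `"t"`, or a numeric vector (then `dof` is
#'   required).
#' @param dof Degrees of freedom; taken from the map when omitted.
#' @param sided `"one"` or `"two"`.
#' @return A [stat_map] of kind `"p"`.
#' @export
#' @examples
#' pmap_from_tmap(stat_map(0, "t", dof = 10))$data   # 0.5
pmap_from_tmap <- function(t, dof = NULL, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (inherits(t, "stat_map")) {
    if (t$kind != "t") stop("input map must hold t statistics", call. = FALSE)
    if (is.null(dof)) dof <- t$dof
    tv <- t$data
    vs <- t$voxel_size
  } else {
    tv <- t
    vs <- NULL
  }
  if (is.null(dof) || dof < 1) stop("dof must be >= 1", call. = FALSE)
  p <- if (sided == "one") stats::pt(tv, df = dof, lower.tail = FALSE)
       else 2 * stats::pt(abs(tv), df = dof, lower.tail = FALSE)
  stat_map(p, "p", dof = dof, voxel_size = vs)
}

#' Sensitivity and specificity at one significance threshold
#'
#' Voxels in the analysis mask with `p < alpha` (strict) are "activated".
#' Sensitivity is the activated fraction of the reference ROI; specificity is
#' one minus the activated fraction of the mask outside the ROI.
#'
#' @param p A p-[stat_map], array or vector.
#' @param roi_ref Logical reference-ROI mask (subset of `analysis_mask`).
#' @param analysis_mask Logical mask of scored voxels.
#' @param alpha Significance threshold.
#' @return A list of class `detection_point`: `alpha`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `n_roi`, `n_out`.
#' @export
sens_spec <- function(p, roi_ref, analysis_mask, alpha) {
  pv <- stat_values(p)
  roi <- as.vector(roi_ref)
  msk <- as.vector(analysis_mask)
  if (any(roi & !msk))
    stop("roi_ref must be a subset of analysis_mask", call. = FALSE)
  n_roi <- sum(roi)
  n_out <- sum(msk & !roi)
  if (n_roi == 0L) stop("roi_ref is empty", call. = FALSE)
  if (n_out == 0L) stop("analysis_mask minus roi_ref is empty", call. = FALSE)
  act <- msk & !is.na(pv) & pv < alpha
  tp <- sum(act & roi)
  fp <- sum(act & !roi)
  structure(list(alpha = alpha, sensitivity = tp / n_roi,
                 specificity = 1 - fp / n_out, tp = tp, fp = fp,
                 n_roi = n_roi, n_out = n_out),
            class = "detection_point")
}

#' Default significance-threshold grid for ROC construction
#'
#' 100 geometrically spaced thresholds from 1e-6 to 0.01 plus 101 linearly
#' spaced from 0.01 to 0.5 (200 unique values): dense low-alpha sampling
#' keeps the AUC discretisation error small where the curve bends fastest.
#'
#' @return Sorted numeric vector of thresholds in (0, 0.5].
#' @export
default_alpha_grid <- function() {
  sort(unique(c(exp(seq(log(1e-6), log(0.01), length.out = 100)),
                seq(0.01, 0.5, length.out = 101))))
}

#' ROC curve and AUC of a p-map against a reference ROI
#'
#' Computes a [sens_spec()] detection point at every grid threshold and the
#' area under the (1-specificity, sensitivity) curve by the trapezoid rule,
#' with anchor points (0,0) and (1,1) appended.
#'
#' @param p A p-[stat_map], array or vector.
#' @param roi_ref,analysis_mask Logical masks as in [sens_spec()].
#' @param alpha_grid Ascending thresholds in (0, 0.5] (default
#'   [default_alpha_grid()]).
#' @return A list of class `roc_result` with `points` (data frame of
#'   threshold, sensitivity, specificity, tp, fp), `auc`, `n_roi`, `n_out`,
#'   `alpha_grid`.
#' @export
roc_curve <- function(p, roi_ref, analysis_mask,
                      alpha_grid = default_alpha_grid()) {
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha_grid must be strictly ascending", call. = FALSE)
  if (any(alpha_grid <= 0 | alpha_grid > 0.5))
    stop("alpha_grid must lie in (0, 0.5]", call. = FALSE)
  pv <- stat_values(p)
  roi <- as.vector(roi_ref)
  msk <- as.vector(analysis_mask)
  if (any(roi & !msk))
    stop("roi_ref must be a subset of analysis_mask", call. = FALSE)
  n_roi <- sum(roi)
  n_out <- sum(msk & !roi)
  if (n_roi == 0L || n_out == 0L)
    stop("roi_ref and its complement within the mask must be non-empty",
         call. = FALSE)
  p_roi <- sort(pv[roi & !is.na(pv)])
  p_out <- sort(pv[msk & !roi & !is.na(pv)])
  # strict inequality p < alpha: left-open interval count via binary search
  tp <- findInterval(alpha_grid, p_roi, left.open = TRUE)
  fp <- findInterval(alpha_grid, p_out, left.open = TRUE)
  sens <- tp / n_roi
  spec <- 1 - fp / n_out
  pts <- data.frame(alpha = alpha_grid, sensitivity = sens,
                    specificity = spec, tp = tp, fp = fp)
  x <- c(0, 1 - spec, 1)
  y <- c(0, sens, 1)
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  auc <- sum(diff(x) * (head_(y, -1) + y[-1]) / 2)
  structure(list(points = pts, auc = auc, n_roi = n_roi, n_out = n_out,
                 alpha_grid = alpha_grid),
            class = "roc_result")
}

head_ <- function(x, n) utils::head(x, n)

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d thresholds, AUC %.4f (ROI %d, non-ROI %d)\n",
              nrow(x$points), x$auc, x$n_roi, x$n_out))
  invisible(x)
}

#' Detection-theory d-prime of a detection point
#'
#' `d' = Z(sensitivity) - Z(1 - specificity)`, `Z` the standard-normal
#' quantile function. Degenerate rates of exactly 0 or 1 give infinite
#' quantiles; with `clip_counts = TRUE` they are replaced by `1/(2n)` and
#' `1 - 1/(2n)` using the relevant voxel counts (the log-linear correction),
#' otherwise they raise an error.
#'
#' @param point A [sens_spec()] detection point.
#' @param clip_counts Apply the `1/(2n)` correction to degenerate rates.
#' @return A list of class `dprime_result`: `dprime`, `alpha`, `clipped`.
#' @export
#' @examples
#' pt <- structure(list(alpha = 0.001, sensitivity = 0.5, specificity = 0.5,
#'                      tp = 5, fp = 5, n_roi = 10, n_out = 10),
#'                 class = "detection_point")
#' dprime(pt)$dprime   # 0
dprime <- function(point, clip_counts = FALSE) {
  stopifnot(inherits(point, "detection_point"))
  sens <- point$sensitivity
  fpr <- 1 - point$specificity
  clipped <- FALSE
  fix <- function(rate, n) {
    if (rate <= 0) { clipped <<- TRUE; 1 / (2 * n) }
    else if (rate >= 1) { clipped <<- TRUE; 1 - 1 / (2 * n) }
    else rate
  }
  if (clip_counts) {
    sens <- fix(sens, point$n_roi)
    fpr <- fix(fpr, point$n_out)
  } else if (sens <= 0 || sens >= 1 || fpr <= 0 || fpr >= 1) {
    stop("degenerate rate (0 or 1) gives infinite d'; use clip_counts = TRUE",
         call. = FALSE)
  }
  structure(list(dprime = stats::qnorm(sens) - stats::qnorm(fpr),
                 alpha = point$alpha, clipped = clipped),
            class = "dprime_result")
}

#' Aggregate per-(subject, contrast) benchmarks
#'
#' Follows the aggregation order of the study design: within each subject the
#' sensitivities and specificities are averaged across contrasts at every
#' threshold, giving one subject-level ROC and AUC; AUC and d' are then
#' summarised as mean and standard deviation over subjects. A pooled mean
#' curve over subjects is emitted for plotting.
#'
#' @param cells List of cells, each a list with fields `subject`, `contrast`,
#'   `roc` (a [roc_curve()] result) and `dprime` (a [dprime()] result).
#' @return A list of class `benchmark_result`: `per_subject` (data frame of
#'   subject, auc, dprime), `auc_mean`, `auc_sd`, `dprime_mean`, `dprime_sd`,
#'   `pooled_curve` (data frame alpha/sensitivity/specificity), `alpha_grid`.
#' @export
aggregate_benchmark <- function(cells) {
  if (!length(cells)) stop("no cells to aggregate", call. = FALSE)
  grids <- lapply(cells, function(cl) cl$roc$alpha_grid)
  if (!all(vapply(grids[-1], identical, TRUE, grids[[1]])))
    stop("all cells must share the same alpha grid", call. = FALSE)
  grid <- grids[[1]]
  subjects <- unique(vapply(cells, function(cl) as.character(cl$subject), ""))
  per_subject <- data.frame(subject = subjects, auc = NA_real_,
                            dprime = NA_real_, stringsAsFactors = FALSE)
  sens_mat <- matrix(0, length(grid), length(subjects))
  spec_mat <- matrix(0, length(grid), length(subjects))
  for (si in seq_along(subjects)) {
    cs <- Filter(function(cl) as.character(cl$subject) == subjects[si], cells)
    sens <- rowMeans(vapply(cs, function(cl) cl$roc$points$sensitivity,
                            numeric(length(grid))))
    spec <- rowMeans(vapply(cs, function(cl) cl$roc$points$specificity,
                            numeric(length(grid))))
    x <- c(0, 1 - spec, 1)
    y <- c(0, sens, 1)
    ord <- order(x, y)
    per_subject$auc[si] <-
      sum(diff(x[ord]) * (head_(y[ord], -1) + y[ord][-1]) / 2)
    per_subject$dprime[si] <-
      mean(vapply(cs, function(cl) cl$dprime$dprime, 0))
    sens_mat[, si] <- sens
    spec_mat[, si] <- spec
  }
  structure(list(
    per_subject = per_subject,
    auc_mean = mean(per_subject$auc),
    auc_sd = stats::sd(per_subject$auc),
    dprime_mean = mean(per_subject$dprime),
    dprime_sd = stats::sd(per_subject$dprime),
    pooled_curve = data.frame(alpha = grid,
                              sensitivity = rowMeans(sens_mat),
                              specificity = rowMeans(spec_mat)),
    alpha_grid = grid
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d subject(s); AUC %.3f +/- %.3f; d' %.3f +/- %.3f\n",
              nrow(x$per_subject), x$auc_mean,
              ifelse(is.na(x$auc_sd), 0, x$auc_sd), x$dprime_mean,
              ifelse(is.na(x$dprime_sd), 0, x$dprime_sd)))
  invisible(x)
}
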