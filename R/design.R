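# HRF-convolved regressor for one condition: boxcars on a fine time grid
# (hrf$step) convolved with the kernel, then sampled at volume acquisition
# times t = volume_index * TR (no slice-timing offset).
condition_regressor <- function(events, condition, n_volumes, TR,
                                hrf = hrf_spec(), kernel = NULL) {
  step <- hrf$step
  if (is.null(kernel)) kernel <- canonical_hrf(hrf)
  ev <- events[events$condition == condition, , drop = FALSE]
  n_fine <- ceiling(n_volumes * TR / step) + 1L
  box <- numeric(n_fine)
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] / step) + 1L
    i1 <- min(n_fine, ceiling((ev$onset[i] + ev$duration[i]) / step))
    box[i0:i1] <- box[i0:i1] + 1
  }
  conv <- stats::convolve(box, rev(as.numeric(kernel)), type = "open")[
    seq_len(n_fine)] * step
  idx <- pmin(n_fine, round((seq_len(n_volumes) - 1) * TR / step) + 1L)
  conv[idx]
}

#' Construct a design matrix from raw columns
#'
#' Low-level constructor used by [build_design_matrix()] and directly in tests
#' or with externally built regressors. Requires exactly one constant column
#' and full column rank.
#'
#' @param x Numeric matrix, `n_volumes x n_regressors`.
#' @param labels Column labels; exactly one must be `"constant"`.
#' @param TR Repetition time in seconds.
#' @return A matrix of class `design_matrix` with attributes `labels` and
#'   `TR`.
#' @export
design_matrix <- function(x, labels = colnames(x), TR) {
  x <- as.matrix(x)
  if (is.null(labels) || length(labels) != ncol(x))
    stop("labels must name every design column", call. = FALSE)
  if (sum(labels == "constant") != 1L)
    stop("the design must contain exactly one 'constant' column", call. = FALSE)
  assert_scalar_num(TR, "TR", lower = 0, strict_lower = TRUE)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- labels[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  colnames(x) <- labels
  structure(x, labels = labels, TR = TR, class = c("design_matrix", "matrix"))
}

#' Build the GLM design matrix for an event paradigm
#'
#' One canonical-HRF regressor and one temporal-derivative regressor per
#' condition present in the events (convolution on the HRF spec's fine grid,
#' sampled at volume times), followed by drift columns, nuisance columns and
#' a constant.
#'
#' @param events An [event_table]; may be empty.
#' @param n_volumes Number of volumes.
#' @param TR Repetition time in seconds.
#' @param hrf An [hrf_spec].
#' @param drift Optional matrix of drift regressors (`n_volumes` rows), e.g.
#'   from [dct_highpass_basis()].
#' @param nuisance Optional matrix of nuisance regressors (`n_volumes` rows),
#'   e.g. from [compcor_regressors()] or motion parameter files.
#' @return A [design_matrix()] with labels `<condition>`,
#'   `<condition>_deriv`, `drift_k`, `nuisance_k`, `constant`.
#' @export
#' @examples
#' ev <- generate_paradigm(60, 1, min_gap = 2, seed = 1)
#' X <- build_design_matrix(ev, 50, 1.2, drift = dct_highpass_basis(50, 1.2, 40))
#' colnames(X)
build_design_matrix <- function(events, n_volumes, TR, hrf = hrf_spec(),
                                drift = NULL, nuisance = NULL) {
  stopifnot(inherits(events, "event_table"))
  n <- as.integer(n_volumes)
  if (nrow(events) && max(events$onset + events$duration) > n * TR)
    stop("events extend beyond the run", call. = FALSE)
  conds <- intersect(localizer_conditions(), unique(events$condition))
  kern_h <- canonical_hrf(hrf)
  kern_d <- hrf_derivative(hrf)
  cols <- list()
  labels <- character()
  for (cc in conds) {
    cols[[length(cols) + 1L]] <-
      condition_regressor(events, cc, n, TR, hrf, kern_h)
    cols[[length(cols) + 1L]] <-
      condition_regressor(events, cc, n, TR, hrf, kern_d)
    labels <- c(labels, cc, paste0(cc, "_deriv"))
  }
  add_block <- function(m, prefix) {
    if (is.null(m) || NCOL(m) == 0L) return(invisible())
    m <- as.matrix(m)
    if (nrow(m) != n)
      stop(prefix, " matrix must have n_volumes rows", call. = FALSE)
    nm <- colnames(m)
    if (is.null(nm)) nm <- paste0(prefix, "_", seq_len(ncol(m)))
    for (j in seq_len(ncol(m))) cols[[length(cols) + 1L]] <<- m[, j]
    labels <<- c(labels, nm)
  }
  add_block(drift, "drift")
  add_block(nuisance, "nuisance")
  cols[[length(cols) + 1L]] <- rep(1, n)
  labels <- c(labels, "constant")
  design_matrix(do.call(cbind, cols), labels, TR)
}

#' Build a contrast weight vector for a design
#'
#' Resolves a catalogue contrast name (weights placed on the canonical
#' regressors of its conditions, zero on derivatives, drift, nuisance and the
#' constant), the special `"mean_signal"` contrast (indicator on the constant
#' column), or explicit named weights over design columns.
#'
#' @param design A [design_matrix()].
#' @param name Contrast name.
#' @param weights Optional named numeric vector of weights keyed by design
#'   column label; overrides the catalogue.
#' @return A list of class `contrast_spec` with fields `name` and `weights`
#'   (full-length numeric vector over design columns).
#' @export
#' @examples
#' ev <- generate_paradigm(320, 3, seed = 1)
#' X <- build_design_matrix(ev, 267, 1.2)
#' contrast_spec(X, "mean_signal")$weights
contrast_spec <- function(design, name, weights = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  labels <- attr(design, "labels")
  w <- stats::setNames(numeric(length(labels)), labels)
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), labels)
    if (length(bad))
      stop("weights name unknown design column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    w[names(weights)] <- weights
  } else if (identical(name, "mean_signal")) {
    w["constant"] <- 1
  } else {
    catalogue <- localizer_contrasts()
    if (!name %in% names(catalogue))
      stop("unknown contrast '", name, "'; supply explicit weights",
           call. = FALSE)
    cw <- catalogue[[name]]
    present <- intersect(names(cw), labels)
    if (!length(present))
      stop("no condition of contrast '", name, "' is present in the design",
           call. = FALSE)
    w[present] <- cw[present]
  }
  if (all(w == 0))
    stop("contrast weights are all zero", call. = FALSE)
  structure(list(name = name, weights = w), class = "contrast_spec")
}
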