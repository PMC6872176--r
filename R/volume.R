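#' Construct a 4D BOLD volume
#'
#' The container every pipeline stage transforms: an (x, y, z, t) array with
#' its repetition time and isotropic voxel size, and an optional brain mask.
#' Voxel indices are 0-based in time (`t = volume_index * TR`) and the
#' geometry is an identity orientation — the benchmark never needs real-world
#' registration.
#'
#' @param data 4D numeric array (x, y, z, t) with `t >= 2`.
#' @param TR Repetition time in seconds.
#' @param voxel_size Isotropic voxel size in mm.
#' @param mask Optional logical 3D array marking brain voxels.
#' @return A list of class `volume4d`.
#' @export
volume4d <- function(data, TR, voxel_size = 1, mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, t)", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("at least 2 time points are required", call. = FALSE)
  assert_scalar_num(TR, "TR", lower = 0, strict_lower = TRUE)
  assert_scalar_num(voxel_size, "voxel_size", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(data)))
    stop("data must be finite", call. = FALSE)
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim(data)[1:3])
  }
  structure(list(data = data, TR = TR, voxel_size = voxel_size, mask = mask),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume4d: %dx%dx%d voxels @ %.3g mm, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], x$voxel_size, d[4], x$TR))
  invisible(x)
}

#' Voxel time series as a matrix
#'
#' @param vol A [volume4d].
#' @return A `t x V` matrix, one column per voxel in array (column-major)
#'   order.
#' @export
as_timeseries_matrix <- function(vol) {
  stopifnot(inherits(vol, "volume4d"))
  d <- dim(vol$data)
  t(matrix(vol$data, prod(d[1:3]), d[4]))
}

# inverse of as_timeseries_matrix
matrix_to_volume <- function(Y, grid, TR, voxel_size, mask = NULL) {
  volume4d(array(t(Y), c(grid, nrow(Y))), TR = TR, voxel_size = voxel_size,
           mask = mask)
}

#' Per-voxel statistic map
#'
#' A scalar per voxel on the grid of a [volume4d] (or a bare vector when no
#' geometry is attached). Undefined voxels are carried as `NA`.
#'
#' @param data 3D numeric array or numeric vector of per-voxel values.
#' @param kind One of `"tsnr"`, `"t"`, `"p"`, `"beta"`.
#' @param dof Degrees of freedom (required for `"t"` and `"p"` maps).
#' @param voxel_size Isotropic voxel size in mm, when known.
#' @return A list of class `stat_map`.
#' @export
stat_map <- function(data, kind = c("tsnr", "t", "p", "beta"), dof = NULL,
                     voxel_size = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("t", "p")) {
    if (is.null(dof) || dof <= 0) stop("t/p maps need dof > 0", call. = FALSE)
  }
  v <- as.vector(data)
  if (kind == "p" && any(v < 0 | v > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (kind == "tsnr" && any(v < 0, na.rm = TRUE))
    stop("tSNR must be >= 0 where defined", call. = FALSE)
  structure(list(data = data, kind = kind, dof = dof,
                 voxel_size = voxel_size),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map (%s): %d voxels, %d undefined%s\n", x$kind,
              length(x$data), sum(is.na(x$data)),
              if (!is.null(x$dof)) sprintf(", dof %.4g", x$dof) else ""))
  invisible(x)
}

# accept a stat_map, array or vector and return a plain numeric vector
stat_values <- function(x) {
  if (inherits(x, "stat_map")) as.vector(x$data) else as.vector(x)
}
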