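#' Read an event table from tab-separated text
#'
#' Expects a header line `onset<TAB>duration<TAB>condition`; onsets and
#' durations in seconds. Parse failures report the offending line number.
#'
#' @param path File path.
#' @param conditions Allowed condition catalogue.
#' @return An [event_table].
#' @export
read_events <- function(path, conditions = localizer_conditions()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("onset", "duration", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  onset <- suppressWarnings(as.numeric(df$onset))
  duration <- suppressWarnings(as.numeric(df$duration))
  check_line <- function(bad, what) {
    if (any(bad))
      stop(sprintf("%s at line %d of %s", what, which(bad)[1] + 1L, path),
           call. = FALSE)
  }
  check_line(is.na(onset), "non-numeric onset")
  check_line(is.na(duration), "non-numeric duration")
  check_line(onset < 0, "negative onset")
  check_line(duration <= 0, "non-positive duration")
  check_line(!df$condition %in% conditions, "unknown condition label")
  event_table(onset, duration, df$condition, conditions = conditions)
}

#' Write an event table as tab-separated text
#'
#' @param events An [event_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a 4D volume or 3D map as NIfTI-1
#'
#' @param x A [volume4d], [stat_map] or logical/numeric 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "volume4d")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(rep(x$voxel_size, 3), x$TR)
  } else if (inherits(x, "stat_map")) {
    a <- x$data
    if (!is.array(a)) stop("stat_map has no grid; cannot write", call. = FALSE)
    vs <- if (is.null(x$voxel_size)) 1 else x$voxel_size
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- rep(vs, 3)
  } else {
    img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a volume or map
#'
#' 4D images become a [volume4d] (TR from the 4th pixdim entry); 3D images
#' are returned as plain arrays with the voxel size in attribute
#' `"voxel_size"`.
#'
#' @param path File path.
#' @return A [volume4d] or 3D array.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  if (length(d) == 4L) {
    volume4d(array(as.numeric(img), d), TR = pd[4], voxel_size = pd[1])
  } else {
    structure(array(as.numeric(img), d), voxel_size = pd[1])
  }
}

#' Write an experiment report as JSON
#'
#' @param report A [run_experiment()] report (or any nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
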