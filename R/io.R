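#' Write and read a multi-echo series as NIfTI plus JSON sidecar
#'
#' The 4D series is stored as NIfTI-1 with dimension order
#' (row, col, echo, frame); the sidecar JSON carries `echo_times_ms`,
#' `frame_times_s`, the paradigm `schedule` and, for phantoms, the exact
#' `ground_truth` generating record at full numeric precision, so the
#' record round-trips losslessly.
#'
#' @param series A `multi_echo_series`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>.json`.
#' @return `write_series()`: the prefix, invisibly. `read_series()`: the
#'   reconstructed `multi_echo_series`.
#' @export
write_series <- function(series, prefix) {
  stopifnot(inherits(series, "multi_echo_series"))
  RNifti::writeNifti(series$data, paste0(prefix, ".nii.gz"))
  sidecar <- list(
    echo_times_ms = series$echo_times,
    frame_times_s = series$frame_times,
    schedule = unclass(series$schedule),
    ground_truth = series$ground_truth
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_series
#' @export
read_series <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  sched <- structure(as.list(side$schedule), class = "paradigm_schedule")
  truth <- side$ground_truth
  if (!is.null(truth$motion_trace)) {
    truth$motion_trace <- matrix(as.integer(truth$motion_trace), ncol = 2)
  }
  multi_echo_series(array(as.numeric(img), dim = dim(img)),
                    side$echo_times_ms, side$frame_times_s, sched,
                    ground_truth = truth)
}

#' Write and read ROI masks as 8-bit NIfTI label images
#'
#' @param roi A [roi_mask()].
#' @param path Output `.nii.gz` path.
#' @param label ROI label to attach on reading.
#' @return `read_roi()`: a [roi_mask()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  RNifti::writeNifti(roi$mask * 1L, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path, label = "other") {
  img <- RNifti::readNifti(path)
  suppressWarnings(roi_mask(matrix(as.integer(img) > 0, nrow = dim(img)[1]),
                            label))
}

#' Write and read T2* time curves as TSV
#'
#' Columns: `time_s`, `t2star_ms`, `n_valid`, `flagged`. The paradigm
#' schedule and ROI label travel in a companion sidecar created by
#' [write_series()] or must be resupplied on reading.
#'
#' @param curve A `t2star_curve`.
#' @param path TSV path.
#' @param schedule A [paradigm_schedule()] to attach on reading.
#' @param roi_label ROI label to attach on reading.
#' @return `read_curve()`: a `t2star_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "t2star_curve"))
  readr::write_tsv(as.data.frame(curve), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, schedule, roi_label = "other") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  new_t2star_curve(tab$time_s, tab$t2star_ms, tab$n_valid, tab$flagged,
                   schedule, roi_label)
}
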