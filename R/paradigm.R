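#' Cuff-occlusion paradigm schedule
#'
#' Describes the timing of a reactive-hyperemia BOLD-MRI examination: a
#' resting baseline, a thigh-cuff occlusion (ischemia) phase, and a
#' reperfusion phase after rapid cuff deflation, sampled at a fixed frame
#' interval. The default schedule is 60 s rest, 300 s occlusion and 300 s
#' reperfusion acquired at one frame every 3.2 s (660 s in total).
#'
#' When `align_release_to_grid` is `TRUE` the cuff-release time is snapped to
#' the nearest frame timestamp by adjusting the occlusion duration; the
#' reperfusion duration is compensated so the total acquisition length is
#' unchanged. This makes noiseless time-to-peak recovery exact whenever the
#' ground-truth peak delay is a multiple of the frame interval.
#'
#' @param rest_duration Baseline (pre-occlusion) duration in seconds.
#' @param occlusion_duration Cuff-compression duration in seconds.
#' @param reperfusion_duration Post-deflation duration in seconds.
#' @param frame_interval Temporal resolution (seconds per frame).
#' @param align_release_to_grid Snap the release time onto the frame grid?
#'
#' @return An object of class `paradigm_schedule`: a list with the three
#'   phase durations, `frame_interval`, and the derived `total_duration`,
#'   `occlusion_start` and `release_time` (all seconds).
#' @examples
#' sched <- paradigm_schedule()
#' sched$total_duration   # 660
#' n_frames(sched)        # 206
#' @export
paradigm_schedule <- function(rest_duration = 60,
                              occlusion_duration = 300,
                              reperfusion_duration = 300,
                              frame_interval = 3.2,
                              align_release_to_grid = TRUE) {
  stopifnot(
    is.numeric(rest_duration), rest_duration > 0,
    is.numeric(occlusion_duration), occlusion_duration > 0,
    is.numeric(reperfusion_duration), reperfusion_duration > 0,
    is.numeric(frame_interval), frame_interval > 0
  )
  release <- rest_duration + occlusion_duration
  if (isTRUE(align_release_to_grid)) {
    snapped <- floor(release / frame_interval + 0.5) * frame_interval
    delta <- snapped - release
    occlusion_duration <- occlusion_duration + delta
    reperfusion_duration <- reperfusion_duration - delta
    if (occlusion_duration <= 0 || reperfusion_duration <= 0) {
      stop("snapping the release time to the frame grid left a non-positive ",
           "phase duration; use a finer frame interval", call. = FALSE)
    }
    release <- snapped
  }
  structure(
    list(
      rest_duration = rest_duration,
      occlusion_duration = occlusion_duration,
      reperfusion_duration = reperfusion_duration,
      frame_interval = frame_interval,
      total_duration = rest_duration + occlusion_duration +
        reperfusion_duration,
      occlusion_start = rest_duration,
      release_time = release
    ),
    class = "paradigm_schedule"
  )
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat("<paradigm_schedule>\n")
  cat(sprintf("  rest %g s | occlusion %g s | reperfusion %g s (total %g s)\n",
              x$rest_duration, x$occlusion_duration, x$reperfusion_duration,
              x$total_duration))
  cat(sprintf("  frame interval %g s (%d frames), release at t = %g s\n",
              x$frame_interval, n_frames(x), x$release_time))
  invisible(x)
}

#' Frame timestamps of a paradigm schedule
#'
#' Frames are stamped with their start times `t_k = k * frame_interval`,
#' `k = 0, 1, ...`; the last frame starts strictly before `total_duration`.
#'
#' @param schedule A [paradigm_schedule()].
#' @return Numeric vector of frame start times in seconds.
#' @export
frame_times <- function(schedule) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  (seq_len(n_frames(schedule)) - 1L) * schedule$frame_interval
}

#' @rdname frame_times
#' @return `n_frames()`: the number of acquired frames.
#' @export
n_frames <- function(schedule) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  dt <- schedule$frame_interval
  as.integer(floor((schedule$total_duration - dt) / dt + 1e-9)) + 1L
}

#' Multi-echo gradient-echo acquisition protocol
#'
#' Scan-protocol parameters of the 2D multi-echo gradient-echo acquisition.
#' Defaults follow the clinical protocol: 11 echoes from 2 to 40 ms,
#' 160 x 160 mm field of view, 128 x 119 acquisition matrix, TR 44 ms,
#' 10 mm slice.
#'
#' @param echo_times Echo times in milliseconds, strictly increasing, all
#'   positive.
#' @param matrix_size Acquisition matrix as `c(rows, cols)`.
#' @param field_of_view Field of view in mm as `c(x, y)`.
#' @param repetition_time Repetition time (TR) in ms.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `acquisition_protocol`.
#' @examples
#' acquisition_protocol()$echo_times
#' @export
acquisition_protocol <- function(echo_times = default_echo_times(),
                                 matrix_size = c(128L, 119L),
                                 field_of_view = c(160, 160),
                                 repetition_time = 44,
                                 slice_thickness = 10) {
  if (!is.numeric(echo_times) || length(echo_times) < 2 ||
      any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop("echo_times must be >= 2 strictly increasing positive values",
         call. = FALSE)
  }
  stopifnot(length(matrix_size) == 2, all(matrix_size >= 1))
  structure(
    list(
      echo_times = as.numeric(echo_times),
      matrix_size = as.integer(matrix_size),
      field_of_view = field_of_view,
      repetition_time = repetition_time,
      slice_thickness = slice_thickness
    ),
    class = "acquisition_protocol"
  )
}

#' @rdname acquisition_protocol
#' @return `default_echo_times()`: the 11 protocol echo times (ms).
#' @export
default_echo_times <- function() {
  c(2, 5.8, 9.6, 13.4, 17.2, 21, 24.8, 28.6, 32.4, 36.2, 40)
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat("<acquisition_protocol>\n")
  cat(sprintf("  %d echoes: %s ms\n", length(x$echo_times),
              paste(x$echo_times, collapse = ", ")))
  cat(sprintf("  matrix %d x %d, FOV %g x %g mm, TR %g ms, slice %g mm\n",
              x$matrix_size[1], x$matrix_size[2], x$field_of_view[1],
              x$field_of_view[2], x$repetition_time, x$slice_thickness))
  invisible(x)
}
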