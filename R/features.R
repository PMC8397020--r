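#' Baseline T2* of a time curve
#'
#' Arithmetic mean of the curve over all frames acquired before cuff
#' inflation (`time < occlusion_start`), i.e. the full resting phase.
#'
#' @param curve A `t2star_curve` (see [extract_roi_curve()]).
#' @return Baseline T2* (BL) in ms.
#' @export
compute_baseline <- function(curve) {
  sched <- curve_schedule(curve)
  sel <- curve$time_s < sched$occlusion_start
  if (!any(sel)) {
    stop("no baseline frames before occlusion start (paradigm error)",
         call. = FALSE)
  }
  mean(curve$t2star_ms[sel])
}

curve_schedule <- function(curve) {
  sched <- attr(curve, "schedule")
  if (!inherits(sched, "paradigm_schedule")) {
    stop("curve carries no paradigm schedule", call. = FALSE)
  }
  sched
}

# centered moving average with shrunken windows at the edges
smooth_curve_values <- function(values, window) {
  if (window %% 2 != 1 || window < 1) {
    stop("smoothing_window must be a positive odd frame count",
         call. = FALSE)
  }
  if (window == 1) return(values)
  h <- (window - 1L) / 2L
  n <- length(values)
  vapply(seq_len(n), function(i) {
    mean(values[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Hyperemia peak of a time curve
#'
#' Optionally smooths the curve with a centered moving average (shrunken
#' windows at the edges; window 1 = no smoothing), restricts to frames at or
#' after cuff release, and locates the maximum of the smoothed values. The
#' hyperemia peak value (HPV) is reported from the same smoothed sequence
#' whose argmax defines the peak; ties go to the earliest time.
#'
#' @param curve A `t2star_curve`.
#' @param smoothing_window Odd positive frame count (default 1).
#' @return A list with `peak_time_abs` (s, absolute acquisition time) and
#'   `hpv` (ms).
#' @export
detect_peak <- function(curve, smoothing_window = 1L) {
  sched <- curve_schedule(curve)
  smoothed <- smooth_curve_values(curve$t2star_ms, smoothing_window)
  sel <- which(curve$time_s >= sched$release_time)
  if (!length(sel)) {
    stop("no reperfusion frames at or after release (paradigm error)",
         call. = FALSE)
  }
  i <- sel[which.max(smoothed[sel])]   # which.max takes the earliest tie
  list(peak_time_abs = curve$time_s[i], hpv = smoothed[i])
}

#' Reactive-hyperemia curve descriptors
#'
#' Composes [compute_baseline()] and [detect_peak()] into the standard
#' descriptor set: baseline T2* (BL), hyperemia peak value (HPV), time to
#' peak after cuff release (TTP = peak time - release time), and overshoot
#' (HPV - BL).
#'
#' @inheritParams detect_peak
#' @return A one-row tibble of class `curve_features` with columns
#'   `roi_label`, `bl_ms`, `hpv_ms`, `ttp_s`, `overshoot_ms`,
#'   `peak_time_s` and `window`.
#' @examples
#' sched <- paradigm_schedule(frame_interval = 4)
#' p <- perfusion_params(24.6, 1.49, 48)
#' tt <- frame_times(sched)
#' curve <- boldperf:::new_t2star_curve(tt, t2star_timecourse(tt, p, sched),
#'   rep(1L, length(tt)), rep(FALSE, length(tt)), sched, "gastrocnemius")
#' extract_features(curve)
#' @export
extract_features <- function(curve, smoothing_window = 1L) {
  sched <- curve_schedule(curve)
  bl <- compute_baseline(curve)
  pk <- detect_peak(curve, smoothing_window)
  out <- tibble::tibble(
    roi_label = attr(curve, "roi_label") %||% NA_character_,
    bl_ms = bl,
    hpv_ms = pk$hpv,
    ttp_s = pk$peak_time_abs - sched$release_time,
    overshoot_ms = pk$hpv - bl,
    peak_time_s = pk$peak_time_abs,
    window = as.integer(smoothing_window)
  )
  class(out) <- c("curve_features", class(out))
  out
}
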