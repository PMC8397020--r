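#' Region-of-interest mask
#'
#' @param mask Logical matrix (row x col); at least one `TRUE` pixel.
#' @param label ROI label: `"gastrocnemius"`, `"soleus"` or `"other"`.
#' @return An object of class `roi_mask` with fields `mask`, `label` and
#'   `pixel_count`. For full-size images (>= 100 rows) a warning is raised
#'   when the pixel count falls outside the 700-1600 range typical of
#'   hand-drawn calf-muscle ROIs; small phantom masks pass silently.
#' @export
roi_mask <- function(mask, label = c("gastrocnemius", "soleus", "other")) {
  label <- match.arg(label)
  if (!is.logical(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask))
  n <- sum(mask)
  if (n == 0) stop("ROI mask is empty", call. = FALSE)
  if (nrow(mask) >= 100 && (n < 700 || n > 1600)) {
    warning("ROI has ", n, " pixels, outside the typical 700-1600 range",
            call. = FALSE)
  }
  structure(list(mask = mask, label = label, pixel_count = n),
            class = "roi_mask")
}

#' Extract a region mask from a phantom geometry
#'
#' @param geometry A [phantom_geometry()].
#' @param region Region name present in `geometry$region_labels`.
#' @return A [roi_mask()].
#' @export
roi_from_geometry <- function(geometry, region = "gastrocnemius") {
  stopifnot(inherits(geometry, "phantom_geometry"),
            region %in% names(geometry$region_labels))
  label <- if (region %in% c("gastrocnemius", "soleus")) region else "other"
  roi_mask(geometry$labels == geometry$region_labels[[region]], label)
}

#' Translation registration of frames to the reference frame
#'
#' For every frame, finds the integer shift within `search_radius` that best
#' aligns the reference (first) frame onto that frame, by maximizing the
#' normalized cross-correlation between the shifted reference first-echo
#' image and the frame's first-echo image. The returned shift is therefore
#' the transform that carries reference-space coordinates (where ROIs are
#' drawn) into the frame's space, and is applied to ROIs, not to the image
#' data. Ties are broken by smallest shift magnitude, then lexicographically
#' by `(dx, dy)`.
#'
#' @param series A `multi_echo_series` with at least one frame.
#' @param search_radius Maximum absolute shift in pixels (>= 0).
#' @return A tibble of class `frame_transforms` with columns `frame`
#'   (1-based), `dx`, `dy` (row/col shift in array index units) and `ncc`.
#'   The reference frame has shift (0, 0).
#' @export
register_frames <- function(series, search_radius = 5L) {
  stopifnot(inherits(series, "multi_echo_series"))
  if (search_radius < 0) stop("search_radius must be >= 0", call. = FALSE)
  search_radius <- as.integer(search_radius)
  d <- dim(series$data)
  nr <- d[1]; nc <- d[2]; nf <- d[4]
  ref <- series$data[, , 1, 1]

  # frames as centered columns for one-pass NCC against each candidate
  M <- matrix(series$data[, , 1, ], nrow = nr * nc, ncol = nf)
  Mc <- sweep(M, 2, colMeans(M))
  Mn <- sqrt(colSums(Mc^2))

  cand <- expand.grid(dx = -search_radius:search_radius,
                      dy = -search_radius:search_radius)
  ord <- order(cand$dx^2 + cand$dy^2, cand$dx, cand$dy)
  cand <- cand[ord, , drop = FALSE]

  best <- rep(-Inf, nf); bi <- rep(1L, nf)
  for (i in seq_len(nrow(cand))) {
    rs <- as.vector(shift_image(ref, cand$dx[i], cand$dy[i]))
    rs <- rs - mean(rs)
    rn <- sqrt(sum(rs^2))
    ncc <- if (rn == 0) rep(NA_real_, nf) else
      as.vector(crossprod(rs, Mc)) / (rn * Mn)
    ncc[!is.finite(ncc)] <- -Inf
    upd <- ncc > best
    best[upd] <- ncc[upd]; bi[upd] <- i
  }
  out <- tibble::tibble(frame = seq_len(nf), dx = cand$dx[bi],
                        dy = cand$dy[bi], ncc = best)
  class(out) <- c("frame_transforms", class(out))
  out
}

#' Apply a frame transform to an ROI mask
#'
#' Translates the mask by the given integer shift; pixels shifted out of the
#' image are dropped and counted.
#'
#' @param roi A [roi_mask()].
#' @param dx,dy Integer shift in array index units (rows, cols).
#' @return A [roi_mask()] with attribute `n_dropped` (pixels lost at the
#'   border). An ROI shifted entirely out of the image is an error.
#' @export
transform_roi <- function(roi, dx, dy) {
  stopifnot(inherits(roi, "roi_mask"))
  shifted <- shift_image(roi$mask * 1, as.integer(dx), as.integer(dy)) > 0
  n <- sum(shifted)
  if (n == 0) {
    stop("ROI shifted entirely out of the image (degenerate ROI)",
         call. = FALSE)
  }
  out <- suppressWarnings(roi_mask(shifted, roi$label))
  attr(out, "n_dropped") <- roi$pixel_count - n
  out
}

#' Extract the ROI-mean T2* time curve
#'
#' For each frame, the ROI is carried into frame space by that frame's
#' transform and the mean T2* is taken over the valid pixels of the
#' transformed ROI. Frames where fewer than half of the ROI pixels are valid
#' are flagged; a frame with zero valid pixels is an error.
#'
#' @param maps A `dynamic_t2star_map` from [fit_dynamic_maps()].
#' @param roi A [roi_mask()].
#' @param transforms A `frame_transforms` tibble from [register_frames()],
#'   or `NULL` for no motion correction. Frame counts must agree.
#' @return A tibble of class `t2star_curve` with columns `time_s`,
#'   `t2star_ms`, `n_valid` and `flagged`, carrying the schedule and ROI
#'   label as attributes.
#' @export
extract_roi_curve <- function(maps, roi, transforms = NULL) {
  stopifnot(inherits(maps, "dynamic_t2star_map"), inherits(roi, "roi_mask"))
  nf <- dim(maps$t2star)[3]
  if (is.null(transforms)) {
    transforms <- tibble::tibble(frame = seq_len(nf), dx = 0L, dy = 0L)
  }
  if (nrow(transforms) != nf) {
    stop("transform count (", nrow(transforms),
         ") does not match frame count (", nf, ")", call. = FALSE)
  }
  vals <- numeric(nf); nv <- integer(nf); flg <- logical(nf)
  for (k in seq_len(nf)) {
    rk <- if (transforms$dx[k] == 0 && transforms$dy[k] == 0) roi else
      transform_roi(roi, transforms$dx[k], transforms$dy[k])
    sel <- rk$mask & maps$valid[, , k]
    n <- sum(sel)
    if (n == 0) {
      stop("no valid ROI pixels in frame ", k, " (degenerate ROI)",
           call. = FALSE)
    }
    vals[k] <- mean(maps$t2star[, , k][sel])
    nv[k] <- n
    flg[k] <- n < 0.5 * rk$pixel_count
  }
  new_t2star_curve(maps$frame_times, vals, nv, flg, maps$schedule, roi$label)
}

new_t2star_curve <- function(times, values, n_valid, flagged, schedule,
                             roi_label) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  out <- tibble::tibble(time_s = times, t2star_ms = values,
                        n_valid = as.integer(n_valid), flagged = flagged)
  attr(out, "schedule") <- schedule
  attr(out, "roi_label") <- roi_label
  class(out) <- c("t2star_curve", class(out))
  out
}

#' @export
print.t2star_curve <- function(x, ...) {
  cat(sprintf("<t2star_curve> %s, %d frames\n",
              attr(x, "roi_label") %||% "?", nrow(x)))
  NextMethod()
}
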