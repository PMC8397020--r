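#' Weighted least-squares T2* fit for one pixel
#'
#' Fits the negative exponential decay `S_i = s0 * exp(-TE_i / T2*)` to the
#' per-echo magnitudes of a single pixel by linear weighted least squares in
#' the log domain: `ln S_i = ln s0 - TE_i * R2*` with weights `w_i = S_i^2`,
#' the variance-stabilizing weight that makes the log-domain fit first-order
#' equivalent to unweighted fitting in the signal domain; a single
#' reweighting pass (weights recomputed from the first-pass fitted signals)
#' then removes most of the residual noise-induced discrepancy between the
#' two domains. Echoes at or below
#' `signal_floor` are discarded; fewer than `min_echoes` usable echoes marks
#' the fit invalid. A non-negative fitted slope (no measurable decay) maps
#' to the upper clamp bound with the clamp flag set, and the fitted T2* is
#' clamped to `[t2star_min, t2star_max]`.
#'
#' @param signal Numeric vector of per-echo signal magnitudes.
#' @param echo_times Echo times in ms, strictly increasing, same length.
#' @param signal_floor Echoes with signal `<=` this are dropped as
#'   noise-dominated (log of non-positive values is undefined).
#' @param t2star_min,t2star_max Clamp bounds in ms.
#' @param min_echoes Minimum usable echoes for a valid fit (default 3, so
#'   the fit is overdetermined and leaves a residual diagnostic).
#' @return A list with `t2star` (ms), `s0`, `valid`, `clamped`, and
#'   `residual` (weighted RMS of log-domain residuals). Invalid fits carry
#'   `NA` estimates.
#' @examples
#' te <- default_echo_times()
#' fit_t2star_pixel(100 * exp(-te / 25.3), te)$t2star  # 25.3
#' @export
fit_t2star_pixel <- function(signal, echo_times,
                             signal_floor = 1e-6,
                             t2star_min = 1, t2star_max = 200,
                             min_echoes = 3L) {
  check_echo_times(echo_times)
  stopifnot(length(signal) == length(echo_times), length(signal) >= 2)
  res <- wls_fit_matrix(matrix(signal, ncol = 1), echo_times, signal_floor,
                        t2star_min, t2star_max, min_echoes)
  list(t2star = res$t2star[1], s0 = res$s0[1], valid = res$valid[1],
       clamped = res$clamped[1], residual = res$residual[1])
}

check_echo_times <- function(echo_times) {
  if (length(echo_times) < 2 || any(diff(echo_times) <= 0)) {
    stop("echo_times must be strictly increasing (>= 2 echoes)",
         call. = FALSE)
  }
  invisible(echo_times)
}

# vectorized log-linear WLS over the columns of an E x N signal matrix;
# two passes: observed-signal weights, then one reweighting from the fitted
# signals (brings the log-domain fit into close agreement with direct
# signal-domain least squares at moderate SNR)
wls_fit_matrix <- function(S, te, signal_floor, t2star_min, t2star_max,
                           min_echoes) {
  use <- S > signal_floor
  L <- log(ifelse(use, S, 1))            # dummy 0 where weight is 0
  W <- S^2 * use
  nuse <- colSums(use)
  slope <- intercept <- rep(NA_real_, ncol(S))
  valid <- rep(FALSE, ncol(S))
  for (pass in 1:2) {
    sw <- colSums(W)
    sx <- colSums(W * te)
    sy <- colSums(W * L)
    sxx <- colSums(W * te^2)
    sxy <- colSums(W * te * L)
    den <- sw * sxx - sx^2
    valid <- nuse >= min_echoes & den > 0 & sw > 0
    slope <- rep(NA_real_, ncol(S))
    slope[valid] <- (sw * sxy - sx * sy)[valid] / den[valid]
    intercept <- rep(NA_real_, ncol(S))
    intercept[valid] <- (sy[valid] - slope[valid] * sx[valid]) / sw[valid]
    if (pass == 1) {
      fit_log <- outer(te, slope) + rep(intercept, each = length(te))
      W_new <- exp(2 * fit_log) * use
      ok <- valid & colSums(!is.finite(W_new)) == 0
      W[, ok] <- W_new[, ok]
    }
  }

  r2star <- -slope
  t2star <- rep(NA_real_, ncol(S))
  clamped <- rep(FALSE, ncol(S))
  nodecay <- valid & r2star <= 0
  t2star[nodecay] <- t2star_max
  clamped[nodecay] <- TRUE
  pos <- valid & r2star > 0
  t2star[pos] <- 1 / r2star[pos]
  hi <- pos & t2star > t2star_max
  lo <- pos & t2star < t2star_min
  t2star[hi] <- t2star_max; t2star[lo] <- t2star_min
  clamped[hi | lo] <- TRUE

  s0 <- exp(intercept)
  fitted <- outer(te, slope) + rep(intercept, each = length(te))
  resid2 <- colSums(W * (L - fitted)^2)
  residual <- ifelse(valid, sqrt(pmax(resid2, 0) / sw), NA_real_)

  list(t2star = t2star, s0 = s0, valid = valid, clamped = clamped,
       residual = residual)
}

#' Dynamic T2* mapping over a whole series
#'
#' Applies [fit_t2star_pixel()] independently to every pixel of every frame
#' of a multi-echo series, producing per-frame T2* and S0 maps with a
#' validity mask. Pixels outside `mask` (when given) are left invalid and
#' are not fitted; pixel ordering has no influence on the estimates. When
#' `signal_floor` is `NULL` it is set to
#' `max(1e-6, 3 * sigma_bg)` with `sigma_bg` estimated from the image
#' border of the first frame.
#'
#' @param series A `multi_echo_series`.
#' @param mask Optional logical matrix (row x col) restricting the fit.
#' @param signal_floor,t2star_min,t2star_max,min_echoes See
#'   [fit_t2star_pixel()].
#' @param frame_chunk Number of frames fitted per vectorized block (memory
#'   control only; results are identical for any chunking).
#' @return An object of class `dynamic_t2star_map`: list with 3D arrays
#'   (row x col x frame) `t2star`, `s0`, `fit_residual` (NA where invalid),
#'   logical arrays `valid` and `clamped`, plus `frame_times` and
#'   `schedule`.
#' @export
fit_dynamic_maps <- function(series, mask = NULL, signal_floor = NULL,
                             t2star_min = 1, t2star_max = 200,
                             min_echoes = 3L, frame_chunk = 512L) {
  stopifnot(inherits(series, "multi_echo_series"))
  d <- dim(series$data)
  nr <- d[1]; nc <- d[2]; ne <- d[3]; nf <- d[4]
  te <- series$echo_times
  check_echo_times(te)

  if (is.null(mask)) {
    mask <- matrix(TRUE, nr, nc)
  } else {
    if (!is.logical(mask)) mask <- mask > 0
    if (!all(dim(mask) == c(nr, nc))) {
      stop("mask shape does not match the image", call. = FALSE)
    }
  }
  if (is.null(signal_floor)) {
    signal_floor <- max(1e-6, 3 * estimate_background_sigma(series))
  }

  idx <- which(mask)
  np <- length(idx)
  mk <- function() array(NA_real_, dim = c(nr, nc, nf))
  t2star <- mk(); s0 <- mk(); residual <- mk()
  valid <- array(FALSE, dim = c(nr, nc, nf))
  clamped <- array(FALSE, dim = c(nr, nc, nf))
  if (np == 0) stop("mask selects no pixels", call. = FALSE)

  flat <- array(series$data, dim = c(nr * nc, ne, nf))
  for (start in seq(1, nf, by = frame_chunk)) {
    fr <- start:min(start + frame_chunk - 1L, nf)
    block <- flat[idx, , fr, drop = FALSE]              # P x E x F'
    S <- matrix(aperm(block, c(2, 1, 3)), nrow = ne)    # E x (P*F')
    fit <- wls_fit_matrix(S, te, signal_floor, t2star_min, t2star_max,
                          min_echoes)
    off <- rep((fr - 1L) * (nr * nc), each = np) + rep.int(idx, length(fr))
    t2star[off] <- fit$t2star
    s0[off] <- fit$s0
    residual[off] <- fit$residual
    valid[off] <- fit$valid
    clamped[off] <- fit$clamped
  }

  structure(
    list(t2star = t2star, s0 = s0, valid = valid, clamped = clamped,
         fit_residual = residual, frame_times = series$frame_times,
         schedule = series$schedule, signal_floor = signal_floor),
    class = "dynamic_t2star_map"
  )
}

# background noise level from a 2-pixel border ring of the first frame
estimate_background_sigma <- function(series) {
  d <- dim(series$data)
  nr <- d[1]; nc <- d[2]
  b <- min(2L, nr %/% 4L, nc %/% 4L)
  if (b < 1) return(0)
  ring <- matrix(FALSE, nr, nc)
  ring[c(seq_len(b), nr - seq_len(b) + 1L), ] <- TRUE
  ring[, c(seq_len(b), nc - seq_len(b) + 1L)] <- TRUE
  vals <- series$data[, , , 1][ring]
  stats::sd(vals)
}

#' @export
print.dynamic_t2star_map <- function(x, ...) {
  d <- dim(x$t2star)
  cat(sprintf("<dynamic_t2star_map> %d x %d pixels, %d frames\n",
              d[1], d[2], d[3]))
  cat(sprintf("  valid %d / %d fits, %d clamped\n", sum(x$valid),
              length(x$valid), sum(x$clamped)))
  invisible(x)
}
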