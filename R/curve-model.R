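#' Ground-truth perfusion curve parameters
#'
#' Parameters of the piecewise ground-truth T2* response of one muscle region
#' to the cuffing paradigm: a constant baseline during rest, a
#' mono-exponential decline toward a floor during occlusion, and a
#' gamma-variate reactive-hyperemia transient after cuff release whose
#' maximum lies exactly `ttp` seconds after release at value
#' `t2star_baseline + overshoot`.
#'
#' @param t2star_baseline Resting T2* (ms); the ground-truth BL.
#' @param overshoot Hyperemia peak minus baseline (ms); may be near zero or
#'   negative in diseased muscle. Ground-truth HPV is
#'   `t2star_baseline + overshoot`.
#' @param ttp Time to peak (s): delay from cuff release to the T2* maximum.
#' @param t2star_occlusion_floor Asymptotic T2* (ms) of the ischemic decline;
#'   must satisfy `0 < floor < baseline`. Default `baseline - 3`.
#' @param occlusion_decay_tau Time constant (s) of the ischemic decline.
#' @param recovery_shape_alpha Shape exponent of the gamma-variate recovery
#'   (dimensionless, > 0). Larger values sharpen the peak.
#' @param s0 Proton-density signal amplitude at TE = 0 (arbitrary units).
#' @return An object of class `perfusion_params`.
#' @examples
#' p <- perfusion_params(t2star_baseline = 24.6, overshoot = 1.49, ttp = 48)
#' @export
perfusion_params <- function(t2star_baseline,
                             overshoot,
                             ttp,
                             t2star_occlusion_floor = t2star_baseline - 3,
                             occlusion_decay_tau = 60,
                             recovery_shape_alpha = 2,
                             s0 = 100) {
  stopifnot(
    is.numeric(t2star_baseline), is.numeric(overshoot), is.numeric(ttp),
    t2star_occlusion_floor > 0, t2star_baseline > t2star_occlusion_floor,
    ttp > 0, occlusion_decay_tau > 0, recovery_shape_alpha > 0, s0 > 0
  )
  structure(
    list(
      t2star_baseline = t2star_baseline,
      overshoot = overshoot,
      ttp = ttp,
      t2star_occlusion_floor = t2star_occlusion_floor,
      occlusion_decay_tau = occlusion_decay_tau,
      recovery_shape_alpha = recovery_shape_alpha,
      s0 = s0
    ),
    class = "perfusion_params"
  )
}

#' Ground-truth T2* time course
#'
#' Evaluates the piecewise ground-truth T2* curve at times `t`:
#' \describe{
#'   \item{rest, `t < occlusion_start`}{constant `t2star_baseline`;}
#'   \item{occlusion}{`floor + (baseline - floor) * exp(-(t - occlusion_start)
#'     / occlusion_decay_tau)`;}
#'   \item{reperfusion, `tau = t - release_time >= 0`}{`T2rel + (peak - T2rel)
#'     * (tau/ttp)^alpha * exp(alpha * (1 - tau/ttp))` with `T2rel` the
#'     occlusion value at release and `peak = baseline + overshoot`.}
#' }
#' The gamma-variate factor equals 1 exactly at `tau = ttp`, so the
#' reperfusion maximum is `peak` at `release_time + ttp` (assuming
#' `peak > T2rel`).
#'
#' @param t Time(s) in seconds, each within `[0, total_duration]`.
#' @param params A [perfusion_params()] object.
#' @param schedule A [paradigm_schedule()].
#' @return Numeric vector of T2* values (ms), same length as `t`.
#' @examples
#' sched <- paradigm_schedule(align_release_to_grid = FALSE)
#' p <- perfusion_params(24.6, 1.49, 48)
#' t2star_timecourse(sched$release_time + 48, p, sched)  # 26.09
#' @export
t2star_timecourse <- function(t, params, schedule) {
  stopifnot(inherits(params, "perfusion_params"),
            inherits(schedule, "paradigm_schedule"))
  if (any(t < 0) || any(t > schedule$total_duration)) {
    stop("t outside the paradigm [0, ", schedule$total_duration, "] s",
         call. = FALSE)
  }
  bl <- params$t2star_baseline
  fl <- params$t2star_occlusion_floor
  tau_occ <- params$occlusion_decay_tau
  alpha <- params$recovery_shape_alpha
  t_occ <- schedule$occlusion_start
  t_rel <- schedule$release_time
  peak <- bl + params$overshoot
  t2_rel <- fl + (bl - fl) * exp(-(t_rel - t_occ) / tau_occ)

  out <- rep(bl, length(t))
  occ <- t >= t_occ & t < t_rel
  out[occ] <- fl + (bl - fl) * exp(-(t[occ] - t_occ) / tau_occ)
  rep <- t >= t_rel
  if (any(rep)) {
    tau <- (t[rep] - t_rel) / params$ttp
    out[rep] <- t2_rel + (peak - t2_rel) * tau^alpha * exp(alpha * (1 - tau))
  }
  out
}
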