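#' Cohort-level generating distributions
#'
#' Group-level means and SDs driving the synthetic cohort: per muscle region
#' the baseline T2* (BL, ms), overshoot (ms) and time to peak (TTP, s), and
#' per group the ankle-brachial index (ABI). Defaults are the published
#' group summaries for 22 PAOD patients and 10 healthy elderly controls.
#'
#' @param n_paod,n_control Group sizes (>= 1).
#' @param seed Integer seed; the whole cohort draw is deterministic given it.
#' @param severity_coupling Coupling strength in `[0, 1]` between a latent
#'   per-subject disease-severity quantile and the (TTP, ABI) draws: higher
#'   severity raises TTP and lowers ABI in both regions. 1 makes TTP and ABI
#'   comonotone (Spearman rho exactly -1 within a group); 0 makes them
#'   independent. The default 0.8 reflects the strong negative TTP-ABI
#'   association without being calibrated to any printed coefficient.
#' @param group_stats Nested list of generating distributions; see
#'   `default_group_stats()`. Each leaf is `c(mean, sd)`.
#' @return An object of class `cohort_params`.
#' @examples
#' cp <- cohort_params(seed = 1)
#' @export
cohort_params <- function(n_paod = 22L, n_control = 10L, seed = 1L,
                          severity_coupling = 0.8,
                          group_stats = default_group_stats()) {
  stopifnot(n_paod >= 1, n_control >= 1,
            severity_coupling >= 0, severity_coupling <= 1)
  sds <- unlist(lapply(group_stats, function(g) {
    c(g$abi[2], vapply(g$regions, function(r)
      c(r$bl[2], r$overshoot[2], r$ttp[2]), numeric(3)))
  }))
  stopifnot(all(sds >= 0))
  structure(
    list(n_paod = as.integer(n_paod), n_control = as.integer(n_control),
         seed = as.integer(seed), severity_coupling = severity_coupling,
         group_stats = group_stats),
    class = "cohort_params"
  )
}

#' @rdname cohort_params
#' @export
default_group_stats <- function() {
  list(
    PAOD = list(
      abi = c(0.65, 0.23),
      regions = list(
        gastrocnemius = list(bl = c(25.3, 2.9), overshoot = c(0.59, 0.93),
                             ttp = c(111, 46)),
        soleus = list(bl = c(21.2, 2.8), overshoot = c(1.59, 0.96),
                      ttp = c(100, 42))
      )
    ),
    control = list(
      abi = c(1.13, 0.09),
      regions = list(
        gastrocnemius = list(bl = c(24.6, 4.1), overshoot = c(1.49, 1.22),
                             ttp = c(48, 22)),
        soleus = list(bl = c(20.8, 3.9), overshoot = c(1.81, 1.86),
                      ttp = c(41, 30))
      )
    )
  )
}

# mean of a normal(mean, sd) truncated to (lower, Inf)
truncated_normal_mean <- function(mean, sd, lower = 0) {
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# positive-truncated normal by resampling (used for standalone draws)
draw_truncated_normal <- function(n, mean, sd, lower = 0) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] <= lower]
  }
  out
}

# quantile of the normal(mean, sd) truncated to (lower, Inf), evaluated at
# the standard-normal quantile of z: monotone in z, exact truncated marginal
qtrunc_normal_z <- function(z, mean, sd, lower = 0) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::pnorm(z) * (1 - p0), mean, sd)
}

# one subject's coupled draw. TTP is obtained by pushing the coupled latent
# Gaussian through the positive-truncated normal inverse CDF, so its
# marginal is exactly the truncated generating distribution, the monotone
# TTP-ABI coupling survives truncation (coupling 1 stays comonotone), and
# the ABI draw is never biased by TTP truncation. The whole subject is
# redrawn only on the rare ABI <= 0 or BL <= 5 ms violations.
draw_subject_row <- function(stats_g, coupling) {
  sc <- sqrt(coupling); si <- sqrt(1 - coupling)
  repeat {
    z_sev <- stats::qnorm(stats::runif(1))
    abi <- stats_g$abi[1] - stats_g$abi[2] *
      (sc * z_sev + si * stats::rnorm(1))
    vals <- lapply(stats_g$regions, function(rg) {
      z_ttp <- sc * z_sev + si * stats::rnorm(1)
      list(
        bl = stats::rnorm(1, rg$bl[1], rg$bl[2]),
        overshoot = stats::rnorm(1, rg$overshoot[1], rg$overshoot[2]),
        ttp = qtrunc_normal_z(z_ttp, rg$ttp[1], rg$ttp[2], lower = 0)
      )
    })
    ok <- abi > 0 && all(vapply(vals, function(v) v$bl > 5, logical(1)))
    if (ok) return(list(abi = abi, regions = vals, severity = z_sev))
  }
}

#' Draw a synthetic cohort's subject parameters
#'
#' Samples per-subject ground-truth parameters for a two-group cohort. Each
#' subject has a latent severity quantile shared (through
#' `severity_coupling`) by the TTP draws of both regions and, with opposite
#' sign, by the ABI draw, so that longer TTP associates with lower ABI. TTP
#' marginals are normal truncated to positive values (via the truncated
#' inverse CDF of the coupled latent quantile, which leaves the ABI draw
#' unbiased).
#'
#' @param params A [cohort_params()].
#' @param snr Target signal-to-noise ratio at the first echo, used to set
#'   each subject's `noise_sigma` (`Inf` = noiseless).
#' @param motion_amplitude Standard deviation (pixels) of an integer
#'   random-walk motion trace; 0 (default) disables motion. The trace itself
#'   is drawn later, in [generate_cohort()], once the frame count is known.
#' @return A tibble with one row per subject: `subject_id`, `group`, `abi`,
#'   `noise_sigma`, per-region ground-truth columns
#'   (`bl_<region>`, `overshoot_<region>`, `ttp_<region>`), and a `regions`
#'   list-column of [perfusion_params()].
#' @examples
#' draw_cohort_params(cohort_params(n_paod = 2, n_control = 2, seed = 7))
#' @export
draw_cohort_params <- function(params, snr = 50, motion_amplitude = 0) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  groups <- c(rep("PAOD", params$n_paod), rep("control", params$n_control))
  ids <- sprintf("%s%02d", ifelse(groups == "PAOD", "P", "C"),
                 c(seq_len(params$n_paod), seq_len(params$n_control)))

  rows <- purrr::map(seq_along(groups), function(i) {
    g <- groups[i]
    d <- draw_subject_row(params$group_stats[[g]], params$severity_coupling)
    region_params <- purrr::map(d$regions, function(v) {
      perfusion_params(t2star_baseline = v$bl, overshoot = v$overshoot,
                       ttp = v$ttp)
    })
    s0 <- region_params[[1]]$s0
    te1 <- default_echo_times()[1]
    sigma <- if (is.finite(snr)) {
      s0 * exp(-te1 / d$regions[[1]]$bl) / snr
    } else 0
    tibble::tibble(
      subject_id = ids[i], group = g, abi = d$abi, noise_sigma = sigma,
      bl_gastrocnemius = d$regions$gastrocnemius$bl,
      overshoot_gastrocnemius = d$regions$gastrocnemius$overshoot,
      ttp_gastrocnemius = d$regions$gastrocnemius$ttp,
      bl_soleus = d$regions$soleus$bl,
      overshoot_soleus = d$regions$soleus$overshoot,
      ttp_soleus = d$regions$soleus$ttp,
      regions = list(region_params)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "motion_amplitude") <- motion_amplitude
  out
}

#' Generate a full synthetic cohort of phantom acquisitions
#'
#' Draws subject parameters with [draw_cohort_params()] and simulates each
#' subject's multi-echo phantom series. Deterministic given
#' `params$seed`.
#'
#' @inheritParams draw_cohort_params
#' @param params A [cohort_params()].
#' @param schedule,protocol,geometry Acquisition configuration; see
#'   [paradigm_schedule()], [acquisition_protocol()], [phantom_geometry()].
#' @param noise_model Passed to [generate_phantom_series()].
#' @return A list with `subjects` (list of elements `series`
#'   (`multi_echo_series`), `subject` ([subject_params()]) and `truth`) and
#'   `table` (the parameter tibble from [draw_cohort_params()]).
#' @export
generate_cohort <- function(params,
                            schedule = paradigm_schedule(),
                            protocol = acquisition_protocol(),
                            geometry = phantom_geometry(),
                            snr = 50, motion_amplitude = 0,
                            noise_model = "gaussian") {
  stopifnot(inherits(params, "cohort_params"))
  tab <- draw_cohort_params(params, snr = snr,
                            motion_amplitude = motion_amplitude)
  nf <- n_frames(schedule)
  subjects <- purrr::map(seq_len(nrow(tab)), function(i) {
    motion <- NULL
    if (motion_amplitude > 0) {
      steps <- matrix(stats::rnorm(2 * nf, 0, motion_amplitude), ncol = 2)
      motion <- apply(round(apply(steps, 2, cumsum) / 4), 2, as.integer)
      motion[1, ] <- 0L
      dim(motion) <- c(nf, 2)
    }
    subj <- subject_params(tab$subject_id[i], tab$group[i], tab$abi[i],
                           regions = tab$regions[[i]],
                           motion_trace = motion,
                           noise_sigma = tab$noise_sigma[i])
    series <- generate_phantom_series(geometry, subj, schedule, protocol,
                                      noise_model = noise_model)
    list(series = series, subject = subj, truth = series$ground_truth)
  })
  list(subjects = subjects, table = tab)
}
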