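# shared fixtures, all generated in code

# ground-truth model curve as a t2star_curve (bypasses the imaging stages)
model_curve <- function(params, schedule, roi_label = "gastrocnemius") {
  tt <- frame_times(schedule)
  boldperf:::new_t2star_curve(
    tt, t2star_timecourse(tt, params, schedule),
    rep(1L, length(tt)), rep(FALSE, length(tt)), schedule, roi_label
  )
}

control_gastroc_params <- function() perfusion_params(24.6, 1.49, 48)
paod_gastroc_params <- function() perfusion_params(25.3, 0.59, 111)

small_subject <- function(regions = NULL, noise_sigma = 0,
                          motion_trace = NULL, group = "control",
                          abi = 1.1) {
  if (is.null(regions)) {
    regions <- list(gastrocnemius = control_gastroc_params(),
                    soleus = perfusion_params(20.8, 1.81, 41))
  }
  subject_params("t01", group, abi, regions = regions,
                 motion_trace = motion_trace, noise_sigma = noise_sigma)
}

# brute-force signal-domain grid-search oracle for the exponential fit
grid_search_t2star <- function(signal, te, t2_range = c(10, 50),
                               s0_range = c(60, 140), n_grid = 200) {
  t2_grid <- seq(t2_range[1], t2_range[2], length.out = n_grid)
  s0_grid <- seq(s0_range[1], s0_range[2], length.out = n_grid)
  best <- Inf; best_t2 <- NA
  decay <- exp(-outer(te, 1 / t2_grid))      # E x n_grid
  for (s0 in s0_grid) {
    sse <- colSums((signal - s0 * decay)^2)
    i <- which.min(sse)
    if (sse[i] < best) { best <- sse[i]; best_t2 <- t2_grid[i] }
  }
  best_t2
}

# permutation-enumeration oracle for the two-sided Mann-Whitney p-value,
# computing U by pairwise comparison counts (a route independent of ranks)
mwu_permutation_oracle <- function(x, y) {
  u_pairwise <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  u_obs <- u_pairwise(x, y)
  idx <- utils::combn(n, n1)
  u_all <- apply(idx, 2, function(i) u_pairwise(pooled[i], pooled[-i]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
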