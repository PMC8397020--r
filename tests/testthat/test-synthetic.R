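test_that("default paradigm yields 206 frames and correct signal decay", {
  geom <- phantom_geometry(c(16, 16))
  sched <- paradigm_schedule()
  subj <- small_subject()
  series <- generate_phantom_series(geom, subj, sched)
  expect_equal(dim(series$data), c(16L, 16L, 11L, 206L))

  # homogeneous region: identical decay across pixels at each frame
  idx <- which(geom$labels == 1L)
  frame1 <- matrix(series$data[, , , 1], nrow = 256)[idx, ]
  expect_true(all(apply(frame1, 2, function(v) diff(range(v)) == 0)))

  # closed-form exponential: TE = 40 with T2* = 20 gives s0 * exp(-2)
  p20 <- perfusion_params(20, 1, 48, s0 = 100)
  s2 <- generate_phantom_series(
    geom, small_subject(regions = list(gastrocnemius = p20, soleus = p20)),
    sched)
  px <- idx[1]
  te <- s2$echo_times
  sig <- matrix(s2$data[, , , 1], nrow = 256)[px, ]
  expect_equal(sig[te == 40], 100 * exp(-40 / 20) * sig[te == 2] /
                 (100 * exp(-2 / 20)), tolerance = 1e-12)
  expect_equal(sig[te == 40], 100 * exp(-2), tolerance = 1e-12)

  # background carries no signal
  expect_true(all(series$data[1, 1, , ] == 0))
})

test_that("cohort generation is deterministic given the seed", {
  cp <- cohort_params(n_paod = 2, n_control = 2, seed = 11)
  sched <- paradigm_schedule(frame_interval = 60)
  a <- generate_cohort(cp, schedule = sched,
                       geometry = phantom_geometry(c(16, 16)), snr = 40)
  b <- generate_cohort(cp, schedule = sched,
                       geometry = phantom_geometry(c(16, 16)), snr = 40)
  expect_identical(a$table, b$table)
  expect_identical(a$subjects[[3]]$series$data, b$subjects[[3]]$series$data)
  expect_equal(sum(a$table$group == "PAOD"), 2)
})

test_that("default cohort sizes match the study groups", {
  tab <- draw_cohort_params(cohort_params(seed = 5))
  expect_equal(sum(tab$group == "PAOD"), 22)
  expect_equal(sum(tab$group == "control"), 10)
})

test_that("ground-truth record round-trips through NIfTI + sidecar", {
  geom <- phantom_geometry(c(16, 16))
  sched <- paradigm_schedule(frame_interval = 30)
  motion <- matrix(0L, n_frames(sched), 2)
  motion[3, ] <- c(1L, -1L)
  subj <- small_subject(noise_sigma = 1.5, motion_trace = motion)
  set.seed(1)
  series <- generate_phantom_series(geom, subj, sched)
  prefix <- tempfile()
  write_series(series, prefix)
  back <- read_series(prefix)
  expect_equal(back$echo_times, series$echo_times)
  expect_equal(back$frame_times, series$frame_times)
  expect_equal(back$ground_truth$regions, series$ground_truth$regions)
  expect_equal(back$ground_truth$abi, series$ground_truth$abi)
  expect_equal(back$ground_truth$motion_trace,
               series$ground_truth$motion_trace)
  expect_equal(back$schedule$release_time, series$schedule$release_time)
  expect_equal(max(abs(back$data - series$data)), 0, tolerance = 1e-6)
})

test_that("comonotone coupling gives Spearman rho(TTP, ABI) = -1 per group", {
  cp <- cohort_params(n_paod = 12, n_control = 8, seed = 3,
                      severity_coupling = 1)
  tab <- draw_cohort_params(cp)
  for (g in c("PAOD", "control")) {
    sub <- tab[tab$group == g, ]
    expect_equal(spearman_rho(sub$ttp_gastrocnemius, sub$abi)$rho, -1)
    expect_equal(spearman_rho(sub$ttp_soleus, sub$abi)$rho, -1)
  }
})

test_that("ABI sampler mean matches its generating distribution at large n", {
  cp <- cohort_params(n_paod = 1, n_control = 1000, seed = 17)
  tab <- draw_cohort_params(cp)
  abi <- tab$abi[tab$group == "control"]
  se <- 0.09 / sqrt(1000)
  expect_lt(abs(mean(abi) - 1.13), 3 * se)
})

test_that("positive truncation bias of the PAOD TTP draw is small and exact", {
  # the generator's truncated draw (inverse-CDF route) agrees with both the
  # analytic truncated-normal mean and an independent rejection sampler
  for (ms in list(c(111, 46), c(100, 42))) {
    analytic <- boldperf:::truncated_normal_mean(ms[1], ms[2], 0)
    set.seed(23)
    mc_gen <- mean(boldperf:::qtrunc_normal_z(rnorm(40000), ms[1], ms[2]))
    mc_rej <- mean(boldperf:::draw_truncated_normal(40000, ms[1], ms[2]))
    expect_equal(mc_gen, analytic, tolerance = 0.01)
    expect_equal(mc_rej, analytic, tolerance = 0.01)
  }
  # soleus (100 +/- 42): excess below 1 s; gastrocnemius (111 +/- 46) sits
  # marginally above at 1.006 s
  expect_lt(boldperf:::truncated_normal_mean(100, 42, 0) - 100, 1)
  expect_equal(boldperf:::truncated_normal_mean(111, 46, 0) - 111, 1.006,
               tolerance = 1e-3)
})

test_that("noise models respect the non-negativity invariant", {
  geom <- phantom_geometry(c(16, 16))
  sched <- paradigm_schedule(frame_interval = 60)
  for (nm in c("gaussian", "rician")) {
    set.seed(9)
    s <- generate_phantom_series(geom, small_subject(noise_sigma = 5),
                                 sched, noise_model = nm)
    expect_true(all(s$data >= 0))
  }
})
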