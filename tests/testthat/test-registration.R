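sched6 <- paradigm_schedule(frame_interval = 110)  # 6 frames, fast

make_moving_series <- function(motion, geom = phantom_geometry(c(24, 24))) {
  generate_phantom_series(geom, small_subject(motion_trace = motion), sched6)
}

test_that("motion-free phantom registers to all-zero shifts", {
  series <- make_moving_series(NULL)
  tr <- register_frames(series, search_radius = 3)
  expect_true(all(tr$dx == 0L & tr$dy == 0L))
  expect_equal(tr$dx[1], 0L)
})

test_that("known applied sampling shifts are recovered with opposite sign", {
  nf <- n_frames(sched6)
  motion <- matrix(0L, nf, 2)
  motion[3, ] <- c(2L, -1L)
  motion[5, ] <- c(-3L, 2L)
  series <- make_moving_series(motion)
  tr <- register_frames(series, search_radius = 4)
  expect_equal(c(tr$dx[3], tr$dy[3]), c(-2L, 1L))
  expect_equal(c(tr$dx[5], tr$dy[5]), c(3L, -2L))
  expect_equal(c(tr$dx[2], tr$dy[2]), c(0L, 0L))
})

test_that("registration is invariant to global intensity scaling of a frame", {
  nf <- n_frames(sched6)
  motion <- matrix(0L, nf, 2); motion[4, ] <- c(1L, 1L)
  series <- make_moving_series(motion)
  series$data[, , , 4] <- series$data[, , , 4] * 3.7
  tr <- register_frames(series, search_radius = 3)
  expect_equal(c(tr$dx[4], tr$dy[4]), c(-1L, -1L))
})

test_that("ties break toward the smallest, lexicographically first shift", {
  # constant frames: every shift correlates identically (NCC undefined),
  # so the first candidate in (magnitude, dx, dy) order - (0,0) - wins
  series <- make_moving_series(NULL)
  series$data[] <- 1
  tr <- register_frames(series, search_radius = 2)
  expect_true(all(tr$dx == 0L & tr$dy == 0L))
  expect_error(register_frames(series, search_radius = -1), "search_radius")
})

test_that("ROI translation conserves interior pixels and composes to identity", {
  geom <- phantom_geometry(c(24, 24))
  roi <- roi_from_geometry(geom, "gastrocnemius")
  expect_identical(transform_roi(roi, 0, 0)$mask, roi$mask)

  for (dx in -2:2) for (dy in -2:2) {
    shifted <- transform_roi(roi, dx, dy)
    expect_equal(shifted$pixel_count, roi$pixel_count)  # interior ROI
    back <- transform_roi(shifted, -dx, -dy)
    expect_identical(back$mask, roi$mask)
  }
  expect_error(transform_roi(roi, 50, 0), "degenerate")
})

test_that("full-size ROI size range raises a warning only on large images", {
  big <- matrix(FALSE, 128, 119); big[1:10, 1:10] <- TRUE  # 100 px
  expect_warning(roi_mask(big), "700-1600")
  small <- matrix(FALSE, 24, 24); small[1:5, 1:5] <- TRUE
  expect_silent(roi_mask(small))
  expect_error(roi_mask(matrix(FALSE, 10, 10)), "empty")
})

test_that("curve extraction matches brute-force means and flags sparse frames", {
  geom <- phantom_geometry(c(24, 24))
  set.seed(33)
  series <- make_moving_series(NULL)
  series$data <- series$data + array(abs(rnorm(length(series$data), 0, 1)),
                                     dim = dim(series$data))
  maps <- fit_dynamic_maps(series)
  roi <- roi_from_geometry(geom, "soleus")
  curve <- extract_roi_curve(maps, roi)

  for (k in seq_len(nrow(curve))) {
    sel <- roi$mask & maps$valid[, , k]
    expect_equal(curve$t2star_ms[k], mean(maps$t2star[, , k][sel]))
  }

  # single-pixel ROI equals that pixel's trace
  px <- which(roi$mask, arr.ind = TRUE)[1, ]
  one <- matrix(FALSE, 24, 24); one[px[1], px[2]] <- TRUE
  c1 <- extract_roi_curve(maps, roi_mask(one, "other"))
  expect_equal(c1$t2star_ms, maps$t2star[px[1], px[2], ])

  # all-invalid ROI errors with the frame named
  bg <- matrix(FALSE, 24, 24); bg[1, 1] <- TRUE
  expect_error(extract_roi_curve(maps, roi_mask(bg, "other")), "frame 1")
})

test_that("curve extraction is permutation-invariant over ROI pixels", {
  geom <- phantom_geometry(c(24, 24))
  series <- make_moving_series(NULL)
  maps <- fit_dynamic_maps(series)
  roi <- roi_from_geometry(geom, "gastrocnemius")
  curve <- extract_roi_curve(maps, roi)
  # mean over any pixel ordering is the same set mean
  idx <- sample(which(roi$mask))
  expect_equal(curve$t2star_ms[1],
               mean(maps$t2star[, , 1][idx]))
})

test_that("registration + ROI propagation recovers the motion-free curve", {
  geom <- phantom_geometry(c(24, 24))
  nf <- n_frames(sched6)
  set.seed(5)
  motion <- cbind(sample(-2:2, nf, TRUE), sample(-2:2, nf, TRUE))
  motion[1, ] <- 0L
  still <- make_moving_series(NULL, geom)
  moving <- make_moving_series(motion, geom)
  roi <- roi_from_geometry(geom, "gastrocnemius")

  maps_still <- fit_dynamic_maps(still)
  maps_mov <- fit_dynamic_maps(moving)
  tr <- register_frames(moving, search_radius = 3)
  curve_corr <- extract_roi_curve(maps_mov, roi, tr)
  curve_ref <- extract_roi_curve(maps_still, roi)
  expect_equal(curve_corr$t2star_ms, curve_ref$t2star_ms, tolerance = 1e-9)
})
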