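test_that("segmentation keeps the largest component and flags blank frames", {
  # synthetic ellipse frame: mask IoU with the true ellipse >= 0.98
  fr <- render_ellipse_frame(120, 40)
  mask <- segment_body(fr)
  n <- nrow(fr)
  cx <- (n + 1) / 2
  xs <- matrix(1:n, n, n, byrow = TRUE)
  ys <- matrix(1:n, n, n)
  truth <- ((xs - cx) / 60)^2 + ((ys - cx) / 20)^2 <= 1
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.98)

  # blank frame -> invalid, not an error
  expect_null(segment_body(matrix(0, 32, 32)))

  # two blobs, one 10x larger -> only the large one kept
  fr2 <- matrix(0, 60, 60)
  fr2[5:8, 5:8] <- 500            # 16 px blob
  fr2[20:40, 20:40] <- 500        # 441 px blob
  m2 <- segment_body(fr2)
  expect_false(any(m2[5:8, 5:8]))
  expect_true(all(m2[20:40, 20:40]))

  # holes are filled
  fr3 <- matrix(0, 40, 40)
  fr3[10:30, 10:30] <- 800
  fr3[18:22, 18:22] <- 0
  expect_true(all(segment_body(fr3)[18:22, 18:22]))
})

test_that("moment ellipse fit recovers axes, symmetry and rotation", {
  # circle: major = minor = 2r
  frc <- render_ellipse_frame(60, 60)
  fit <- fit_ellipse(segment_body(frc))
  expect_lt(abs(fit$major_axis - 60), 0.5)
  expect_lt(abs(fit$minor_axis - 60), 0.5)

  # rotating by 90 degrees leaves axes unchanged, shifts orientation by pi/2
  f0 <- fit_ellipse(segment_body(render_ellipse_frame(100, 40, 0)))
  f90 <- fit_ellipse(segment_body(render_ellipse_frame(100, 40, pi / 2)))
  expect_equal(f0$major_axis, f90$major_axis, tolerance = 0.01)
  expect_equal(f0$minor_axis, f90$minor_axis, tolerance = 0.01)
  expect_equal(abs(f90$orientation - f0$orientation), pi / 2,
               tolerance = 0.02)

  # area consistency: mask area within 10% of pi/4 * major * minor
  expect_lt(abs(f0$area - pi / 4 * 100 * 40) / (pi / 4 * 100 * 40), 0.1)

  expect_error(fit_ellipse(matrix(FALSE, 5, 5)), "empty")
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_error(fit_ellipse(line), "degenerate")
})

test_that("axis recovery error stays below 1.5% across sizes and orientations", {
  errs <- c()
  for (axes in list(c(20, 20), c(30, 20), c(60, 40), c(120, 40), c(200, 100))) {
    for (th in seq(0, pi, length.out = 5)) {
      fr <- render_ellipse_frame(axes[1], axes[2], th)
      fit <- fit_ellipse(segment_body(fr))
      errs <- c(errs, abs(fit$minor_axis - axes[2]) / axes[2],
                abs(fit$major_axis - axes[1]) / axes[1])
    }
  }
  expect_lt(max(errs), 0.015)
})

test_that("fitted axes scale with frame magnification", {
  f1 <- fit_ellipse(segment_body(render_ellipse_frame(60, 24)))
  f2 <- fit_ellipse(segment_body(render_ellipse_frame(120, 48)))
  expect_lt(abs(f2$major_axis / f1$major_axis - 2), 0.02)
  expect_lt(abs(f2$minor_axis / f1$minor_axis - 2), 0.02)
})

test_that("width traces track the generator geometry frame by frame", {
  cfg <- width_assay_config(seed = 3, duration = 900)
  ev <- simulate_events(cfg)
  traj <- simulate_geometry(cfg, ev)
  st <- render_movie(traj, NULL, intensity_scale = 180)
  wt <- compute_width_trace(st, cfg$geometry_frame_rate)
  expect_true(all(wt$valid))
  expect_lt(max(abs(wt$width - traj$width) / traj$width), 0.01)
  # k contractions -> k local maxima of the measured width trace
  pk <- hydrapulse:::local_maxima(wt$width)
  prom <- hydrapulse:::peak_prominence(wt$width, pk)
  expect_equal(sum(prom > 0.05 * diff(range(wt$width))),
               nrow(ev$burst_windows))
})

test_that("constant-geometry movies give constant width traces", {
  traj <- static_trajectory(120, 50)
  st <- render_movie(traj, NULL, frame_shape = c(72, 160),
                     intensity_scale = 150)
  stack <- array(st[, , 1], dim = c(dim(st)[1:2], 5))
  wt <- compute_width_trace(stack, 0.5)
  expect_equal(diff(range(wt$width)), 0)
})

test_that("isolated blank frames are interpolated; too many are an error", {
  traj <- static_trajectory(120, 50)
  good <- render_movie(traj, NULL, frame_shape = c(72, 160),
                       intensity_scale = 150)[, , 1]
  stack <- array(good, dim = c(dim(good), 5))
  stack[, , 3] <- 0
  wt <- compute_width_trace(stack, 0.5)
  expect_true(wt$valid[3])
  expect_equal(wt$width[3], (wt$width[2] + wt$width[4]) / 2)
  bad <- array(0, dim = c(dim(good), 5))
  bad[, , 1] <- good
  expect_error(compute_width_trace(bad, 0.5), "segmented")
})

test_that("cycle detection recovers end-of-elongation minima", {
  # monotone trace -> zero minima, mean reported missing
  wt0 <- structure(list(times = 0:99, width = seq(80, 40, length.out = 100),
                        length = rep(100, 100), valid = rep(TRUE, 100),
                        frame_rate = 1), class = "width_trace")
  cs0 <- detect_cycles(wt0)
  expect_length(cs0$minima_times, 0)
  expect_true(is.na(cs0$mean_end_elongation_width))

  # generator truth: minima within one frame, widths within 2%
  cfg <- width_assay_config(seed = 6, duration = 1800)
  ev <- simulate_events(cfg)
  traj <- simulate_geometry(cfg, ev)
  wt <- structure(list(times = traj$times, width = traj$width,
                       length = traj$length,
                       valid = rep(TRUE, length(traj$times)),
                       frame_rate = traj$frame_rate), class = "width_trace")
  cs <- detect_cycles(wt)
  expect_equal(length(cs$minima_times), length(traj$cycle_minima_times))
  expect_true(all(abs(cs$minima_times - traj$cycle_minima_times) <=
                    1 / traj$frame_rate))
  expect_true(all(abs(cs$minima_widths - traj$cycle_minima_widths) /
                    traj$cycle_minima_widths <= 0.02))

  # two cycles with minima 40 and 44 -> mean 42
  expect_equal(mean(c(40, 44)), 42)
  w2 <- c(seq(80, 40, length.out = 50), seq(40, 80, length.out = 100),
          seq(80, 44, length.out = 100), seq(44, 80, length.out = 50))
  wt2 <- structure(list(times = seq_along(w2), width = w2,
                        length = rep(100, length(w2)),
                        valid = rep(TRUE, length(w2)), frame_rate = 1),
                   class = "width_trace")
  cs2 <- detect_cycles(wt2, min_period = 10)
  expect_equal(cs2$mean_end_elongation_width, 42)
})

test_that("contraction counting uses the shortening threshold", {
  # constant length -> 0
  wt0 <- structure(list(times = 0:49, width = rep(50, 50),
                        length = rep(120, 50), valid = rep(TRUE, 50),
                        frame_rate = 1), class = "width_trace")
  expect_equal(count_contractions(wt0), 0)

  # sub-threshold wiggles (10% shortening vs 30% threshold) -> 0
  len <- 120 + 12 * sin(seq(0, 6 * pi, length.out = 200))
  wt1 <- structure(list(times = seq_along(len), width = rep(50, 200),
                        length = len, valid = rep(TRUE, 200),
                        frame_rate = 1), class = "width_trace")
  expect_equal(count_contractions(wt1, 0.3), 0)

  # generator bursts drive full contractions: count = burst count
  cfg <- width_assay_config(seed = 9, duration = 1800)
  ev <- simulate_events(cfg)
  traj <- simulate_geometry(cfg, ev)
  wt <- structure(list(times = traj$times, width = traj$width,
                       length = traj$length,
                       valid = rep(TRUE, length(traj$times)),
                       frame_rate = traj$frame_rate), class = "width_trace")
  expect_equal(count_contractions(wt, 0.3), nrow(ev$burst_windows))
})

test_that("hyperosmotic geometry ends elongation at a narrower width", {
  # narrower elongated width parameter emulates the high-osmolarity body
  ctr <- width_assay_config(seed = 12, duration = 1800)
  high <- width_assay_config(seed = 12, duration = 1800,
                             condition_label = "high",
                             width_elongated = 30)
  w_ctr <- {
    ev <- simulate_events(ctr)
    traj <- simulate_geometry(ctr, ev)
    mean(traj$cycle_minima_widths)
  }
  w_high <- {
    ev <- simulate_events(high)
    traj <- simulate_geometry(high, ev)
    mean(traj$cycle_minima_widths)
  }
  expect_lt(w_high, w_ctr)
})
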