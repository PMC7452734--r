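test_that("normalisation zeroes constant traces and is scale invariant", {
  tr <- fluor_trace(rep(50, 400), frame_rate = 2)
  dff <- normalize_trace(tr)
  expect_true(all(abs(dff$values) < 1e-12))
  set.seed(2)
  vals <- 100 + 20 * abs(sin(seq(0, 10, length.out = 600))) + rnorm(600)
  d1 <- normalize_trace(fluor_trace(vals, 2))
  d2 <- normalize_trace(fluor_trace(vals * 3.7, 2))
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
  expect_error(normalize_trace(d1), "already")
  expect_error(normalize_trace(fluor_trace(rep(1, 30), 2),
                               baseline_window = 1), "at least 10 frames")
})

test_that("normalisation removes slow photobleaching", {
  cfg <- simulation_config(duration = 7200, bleach_tau = 1800, seed = 21)
  ev <- simulate_events(cfg)
  dff <- normalize_trace(render_trace(ev, cfg), baseline_window = 120)
  # quiet samples far from any pulse: residual baseline drift < 0.02 dF/F
  quiet <- rep(TRUE, length(dff$values))
  for (pt in ev$pulses$time) {
    quiet[dff$times > pt - 4 & dff$times < pt + 10] <- FALSE
  }
  qv <- dff$values[quiet]
  qt <- dff$times[quiet]
  drift <- abs(coef(lm(qv ~ qt))[[2]]) * 7200
  expect_lt(drift, 0.02)
})

test_that("detection returns nothing on flat traces and rejects bad separation", {
  flat <- fluor_trace(rep(0, 500), 2)
  flat$units <- "dff"
  expect_equal(nrow(detect_pulses(flat)), 0)
  expect_error(detect_pulses(flat, min_separation = 0.1),
               "min_separation")
  raw <- fluor_trace(rep(1, 500), 2)
  expect_error(detect_pulses(raw), "dF/F")
})

test_that("noiseless well-separated pulses are found exactly, matching the brute-force scan", {
  cfg <- simulation_config(duration = 600, cb_burst_rate = 0, rp1_rate = 0,
                           noise_sd = 0, bleach_tau = Inf)
  ev <- simulate_events(cfg)
  true_times <- c(50, 150, 250, 350, 450)
  ev$pulses <- data.frame(time = true_times, class = "RP1", burst = NA)
  tr <- render_trace(ev, cfg)
  dff <- normalize_trace(tr)
  p <- detect_pulses(dff)
  expect_equal(nrow(p), 5)
  expect_true(all(abs(p$time - true_times) <= 1 / cfg$frame_rate))
  # oracle equivalence on the smoothed trace at the same threshold
  ys <- hydrapulse:::boxcar_smooth(dff$values, 3L)
  oracle <- brute_force_peaks(ys, attr(p, "threshold"))
  det_idx <- vapply(p$time, function(t) which.min(abs(dff$times - t)),
                    integer(1))
  expect_equal(sort(vapply(det_idx, function(i) {
    # map refined raw peak back to its smoothed local maximum
    oracle[which.min(abs(oracle - i))]
  }, integer(1))), sort(oracle))
})

test_that("raising the threshold never increases the pulse count", {
  cfg <- simulation_config(duration = 1200, seed = 31)
  dff <- normalize_trace(render_trace(simulate_events(cfg), cfg))
  counts <- vapply(c(2, 3, 4, 6, 8, 12),
                   function(k) nrow(detect_pulses(dff, threshold_k = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is accurate on realistic noisy traces", {
  f1 <- vapply(1:5, function(s) {
    cfg <- simulation_config(duration = 3600, seed = 100 + s)
    ev <- simulate_events(cfg)
    res <- analyze_trace(render_trace(ev, cfg))
    score_detection(res$pulses, ev, tolerance = 1)$f1
  }, numeric(1))
  expect_true(all(f1 >= 0.95))
})

test_that("adding slow exponential drift barely changes the CB pulse count", {
  cfg <- simulation_config(duration = 3600, seed = 55, bleach_tau = Inf)
  ev <- simulate_events(cfg)
  tr <- render_trace(ev, cfg)
  base <- analyze_trace(tr)$summary$cb_pulse_number
  drifted <- tr
  drifted$values <- tr$values +
    0.5 * cfg$baseline * exp(-tr$times / 900)  # 50% amplitude, tau 15 min
  with_drift <- analyze_trace(drifted)$summary$cb_pulse_number
  expect_lte(abs(with_drift - base) / base, 0.02)
})

test_that("burst grouping follows the IPI definition", {
  p <- data.frame(time = c(10, 12, 14, 300))
  b <- group_bursts(p, max_ipi = 5, min_pulses = 2)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset, 10)
  expect_equal(b$offset, 14)
  expect_equal(b$n_pulses, 3)
  expect_equal(attr(b, "pulse_burst"), c(1L, 1L, 1L, NA))
  # all gaps above max_ipi -> no bursts
  b2 <- group_bursts(data.frame(time = c(0, 50, 100)), max_ipi = 10,
                     min_pulses = 2)
  expect_equal(nrow(b2), 0)
  # empty input -> empty output
  expect_equal(nrow(group_bursts(data.frame(time = numeric(0)))), 0)
  # padding widens the window symmetrically
  b3 <- group_bursts(p, max_ipi = 5, min_pulses = 2, pad = 1)
  expect_equal(c(b3$onset, b3$offset), c(9, 15))
  expect_error(group_bursts(data.frame(time = c(5, 1))), "sorted")
})

test_that("burst count is recovered on noiseless traces", {
  for (s in 1:5) {
    cfg <- simulation_config(duration = 3600, noise_sd = 0, seed = 200 + s)
    ev <- simulate_events(cfg)
    res <- analyze_trace(render_trace(ev, cfg))
    expect_equal(nrow(res$bursts), nrow(ev$burst_windows))
  }
})

test_that("classification separates CB and RP1 and respects the muscle rule", {
  # all pulses inside bursts -> all CB
  p <- data.frame(time = c(1, 3, 5), amplitude = c(1, 1.1, 0.9))
  b <- group_bursts(p, max_ipi = 5, min_pulses = 2)
  out <- classify_pulses(p, b)
  expect_true(all(out$class == "CB"))

  # mixed neural trace: isolated small -> RP1, isolated large -> unassigned
  p2 <- data.frame(time = c(1, 3, 5, 100, 200),
                   amplitude = c(1, 1.1, 0.9, 0.4, 1.2))
  b2 <- group_bursts(p2, max_ipi = 5, min_pulses = 2)
  out2 <- classify_pulses(p2, b2, amplitude_ratio = 0.7, min_pulses = 2)
  expect_equal(out2$class, c("CB", "CB", "CB", "RP1", "unassigned"))
  out2b <- classify_pulses(p2, b2, amplitude_ratio = 0.7, min_pulses = 1)
  expect_equal(out2b$class[5], "CB")

  # muscle tissue forces the RP1 set empty
  out3 <- classify_pulses(p2, b2, tissue = "ectoderm")
  expect_true(all(out3$class == "CB"))
  expect_equal(sum(out3$class == "RP1"), 0)

  # conservation: CB + RP1 + unassigned = total detected
  cfg <- simulation_config(duration = 1800, seed = 77)
  res <- analyze_trace(render_trace(simulate_events(cfg), cfg))
  expect_equal(sum(table(res$pulses$class)), nrow(res$pulses))
})

test_that("muscle recordings report zero RP1 pulses end to end", {
  cfg <- simulation_config(duration = 1800, rp1_rate = 0, tissue = "ectoderm",
                           seed = 13)
  res <- analyze_trace(render_trace(simulate_events(cfg), cfg))
  expect_equal(res$summary$rp1_pulse_number, 0)
  expect_equal(res$summary$rp1_frequency_per_h, 0)
})

test_that("activity summaries follow their definitions", {
  # no pulses -> all-zero summary
  p0 <- data.frame(time = numeric(0), amplitude = numeric(0),
                   width_s = numeric(0), class = character(0))
  b0 <- group_bursts(p0)
  s0 <- summarize_events(p0, b0, 7200)
  expect_equal(s0$cb_pulse_number, 0)
  expect_equal(s0$cb_pulse_frequency_per_min, 0)
  expect_equal(s0$rp1_total_time_s, 0)

  # one burst of 6 pulses spanning 60 s in a 7200-s recording
  p1 <- data.frame(time = seq(0, 60, length.out = 6),
                   amplitude = rep(1, 6), width_s = rep(2, 6),
                   class = rep("CB", 6))
  b1 <- group_bursts(p1, max_ipi = 15, min_pulses = 2)
  s1 <- summarize_events(p1, b1, 7200)
  expect_equal(s1$cb_pulse_number, 6)
  expect_equal(s1$cb_total_time_s, 60)
  expect_equal(s1$cb_pulse_frequency_per_min, 6)
  expect_equal(s1$burst_count, 1)

  # rp1 totals: sum of half-prominence widths; frequency per hour
  p2 <- data.frame(time = c(100, 200), amplitude = c(0.4, 0.4),
                   width_s = c(2.5, 3.5), class = c("RP1", "RP1"))
  b2 <- group_bursts(p2, max_ipi = 10, min_pulses = 2)
  s2 <- summarize_events(p2, b2, 3600)
  expect_equal(s2$rp1_total_time_s, 6)
  expect_equal(s2$rp1_frequency_per_h, 2)
  expect_error(summarize_events(p2, b2, 0), "duration")
})

test_that("recovered CB pulse numbers track ground truth over many seeds", {
  det <- tru <- numeric(40)
  for (s in 1:40) {
    cfg <- simulation_config(duration = 1200, seed = 300 + s)
    ev <- simulate_events(cfg)
    det[s] <- analyze_trace(render_trace(ev, cfg))$summary$cb_pulse_number
    tru[s] <- sum(ev$pulses$class == "CB")
  }
  expect_lt(abs(mean(det) - mean(tru)) / mean(tru), 0.05)
})

test_that("detection scoring implements greedy matching and the stated conventions", {
  # detected == truth -> perfect score
  s <- score_detection(c(1, 5, 9), c(1, 5, 9), tolerance = 0.5)
  expect_equal(s$f1, 1)
  # empty detected, non-empty truth -> precision 1, recall 0, F1 0
  s2 <- score_detection(numeric(0), c(1, 2), tolerance = 1)
  expect_equal(s2$precision, 1)
  expect_equal(s2$recall, 0)
  expect_equal(s2$f1, 0)
  # 1 of 2 found, no false detections
  s3 <- score_detection(1, c(1, 10), tolerance = 0.5)
  expect_equal(s3$precision, 1)
  expect_equal(s3$recall, 0.5)
  expect_equal(s3$f1, 2 / 3)
  # one-to-one: a single detection cannot match two close truths
  s4 <- score_detection(c(1.1), c(1, 1.2), tolerance = 0.5)
  expect_equal(s4$n_matched, 1)
  expect_error(score_detection(1, 1, tolerance = 0), "tolerance")
})
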