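#' Simulate contraction-elongation body geometry
#'
#' Produces per-frame body-column length and width driven by the
#' ground-truth burst windows: during a burst the posture relaxes towards
#' the contracted state (length down, width up) with time constant
#' `contraction_tau`; between bursts it relaxes towards the elongated
#' state (length up, width down) with `elongation_tau`. Width and length
#' are anti-correlated by construction. The time of minimum width in each
#' inter-contraction interval is recorded as a ground-truth cycle minimum
#' (the end-of-elongation width).
#'
#' @param config A [simulation_config()]; geometry is sampled at
#'   `geometry_frame_rate` (0.5 Hz by default, matching the width assay).
#' @param events A `ground_truth` object from [simulate_events()].
#' @return An object of class `geometry_trajectory`: list with `times`,
#'   `length`, `width` (px), `centroid` (n x 2 px offsets),
#'   `cycle_minima_times`, `cycle_minima_widths`, `frame_rate`.
#' @export
simulate_geometry <- function(config, events) {
  stopifnot(inherits(config, "sim_config"), inherits(events, "ground_truth"))
  fr <- config$geometry_frame_rate
  n <- round(config$duration * fr)
  t <- (seq_len(n) - 1) / fr
  dt <- 1 / fr

  bw <- events$burst_windows
  in_burst <- rep(FALSE, n)
  if (nrow(bw) > 0) {
    for (j in seq_len(nrow(bw))) {
      in_burst[t >= bw$onset[j] & t <= bw$offset[j]] <- TRUE
    }
  }

  # first-order relaxation of the contraction envelope c in [0, 1]
  cenv <- numeric(n)
  cenv[1] <- 0.5
  for (i in 2:n) {
    tau <- if (in_burst[i]) config$contraction_tau else config$elongation_tau
    target <- if (in_burst[i]) 1 else 0
    cenv[i] <- cenv[i - 1] + dt * (target - cenv[i - 1]) / tau
  }

  width <- config$width_elongated +
    (config$width_contracted - config$width_elongated) * cenv
  len <- config$length_elongated -
    (config$length_elongated - config$length_contracted) * cenv

  # ground-truth end-of-elongation minima: one per inter-contraction
  # interval, i.e. the frame of minimum width before each burst onset
  min_t <- numeric(0)
  min_w <- numeric(0)
  if (nrow(bw) > 0) {
    prev_off <- 0
    for (j in seq_len(nrow(bw))) {
      sel <- which(t >= prev_off & t < bw$onset[j])
      if (length(sel) > 1L) {
        k <- sel[which.min(width[sel])]
        min_t <- c(min_t, t[k])
        min_w <- c(min_w, width[k])
      }
      prev_off <- bw$offset[j]
    }
  }

  structure(list(times = t, length = len, width = width,
                 centroid = matrix(0, nrow = n, ncol = 2,
                                   dimnames = list(NULL, c("x", "y"))),
                 cycle_minima_times = min_t,
                 cycle_minima_widths = min_w,
                 frame_rate = fr),
            class = "geometry_trajectory")
}

#' @export
print.geometry_trajectory <- function(x, ...) {
  cat(sprintf(
    "<geometry_trajectory> %d frames at %g Hz, width %.1f-%.1f px, %d cycle minima\n",
    length(x$times), x$frame_rate, min(x$width), max(x$width),
    length(x$cycle_minima_times)))
  invisible(x)
}

#' Render a synthetic width movie
#'
#' Draws, per frame, a filled ellipse (axes = body length and width, fixed
#' orientation) on a dark background, with interior intensity proportional
#' to the fluorescence trace value at that frame (linearly resampled onto
#' the geometry time base). Edge pixels carry fractional intensity from
#' supersampled coverage, emulating optical blur at the body outline.
#'
#' @param traj A `geometry_trajectory`.
#' @param trace A [fluor_trace] sharing the trajectory's time span, or
#'   `NULL` for constant unit intensity times `intensity_scale`.
#' @param frame_shape `c(rows, cols)` of each frame, px.
#' @param orientation Ellipse orientation, radians (major axis from the
#'   x-axis).
#' @param intensity_scale Multiplier applied to the trace value.
#' @param supersample Subsamples per pixel edge for coverage estimation.
#' @param shot_noise If `TRUE`, pixel values are Poisson draws with the
#'   noiseless image as mean.
#' @param seed Seed used for shot noise.
#' @return `h x w x n` integer-valued array in 16-bit intensity units,
#'   with attribute `frame_rate`.
#' @export
render_movie <- function(traj, trace = NULL, frame_shape = c(96, 192),
                         orientation = 0, intensity_scale = 1,
                         supersample = 8L, shot_noise = FALSE, seed = 1L) {
  stopifnot(inherits(traj, "geometry_trajectory"))
  n <- length(traj$times)
  h <- frame_shape[1L]
  w <- frame_shape[2L]
  vals <- if (is.null(trace)) {
    rep(1, n)
  } else {
    stats::approx(trace$times, trace$values, xout = traj$times, rule = 2)$y
  }
  cx <- (w + 1) / 2 + traj$centroid[, 1L]
  cy <- (h + 1) / 2 + traj$centroid[, 2L]
  a <- traj$length / 2
  b <- traj$width / 2
  co <- cos(orientation); si <- sin(orientation)
  ext_x <- sqrt((a * co)^2 + (b * si)^2)
  ext_y <- sqrt((a * si)^2 + (b * co)^2)
  if (any(cx - ext_x < 0.5 | cx + ext_x > w + 0.5 |
          cy - ext_y < 0.5 | cy + ext_y > h + 0.5)) {
    stop("ellipse exceeds frame bounds")
  }

  s <- as.integer(supersample)
  off <- (seq_len(s) - (s + 1) / 2) / s
  sub <- expand.grid(dx = off, dy = off)
  stack <- array(0, dim = c(h, w, n))
  for (i in seq_len(n)) {
    x0 <- max(1L, floor(cx[i] - ext_x[i] - 1)); x1 <- min(w, ceiling(cx[i] + ext_x[i] + 1))
    y0 <- max(1L, floor(cy[i] - ext_y[i] - 1)); y1 <- min(h, ceiling(cy[i] + ext_y[i] + 1))
    xs <- x0:x1; ys <- y0:y1
    X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
    cov <- matrix(0, nrow = length(ys), ncol = length(xs))
    for (k in seq_len(nrow(sub))) {
      u <- (X + sub$dx[k] - cx[i]) * co + (Y + sub$dy[k] - cy[i]) * si
      v <- -(X + sub$dx[k] - cx[i]) * si + (Y + sub$dy[k] - cy[i]) * co
      cov <- cov + ((u / a[i])^2 + (v / b[i])^2 <= 1)
    }
    stack[ys, xs, i] <- cov / nrow(sub) * vals[i] * intensity_scale
  }
  if (shot_noise) {
    stack[] <- withr::with_seed(seed,
      stats::rpois(length(stack), lambda = as.vector(stack)))
  }
  stack <- round(pmin(pmax(stack, 0), 65535))
  attr(stack, "frame_rate") <- traj$frame_rate
  stack
}
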