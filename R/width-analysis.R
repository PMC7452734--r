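#' Segment the animal body in a single frame
#'
#' Otsu threshold refined by isodata iteration (the threshold converges
#' to the midpoint of the background and foreground mean intensities,
#' which places the cut at half coverage on the blurred body outline and
#' removes the rim bias a raw Otsu cut shows on near-binary frames),
#' then keep the largest connected component and fill holes. An empty
#' foreground is reported as an invalid frame rather than an error,
#' since isolated dropped frames are interpolated downstream.
#'
#' @param frame Numeric matrix, single-channel, 16-bit intensity units.
#' @return A logical matrix mask, or `NULL` when the frame has no
#'   foreground.
#' @export
segment_body <- function(frame) {
  stopifnot(is.matrix(frame))
  rng <- range(frame)
  if (rng[2] <= rng[1]) return(NULL)
  thr <- EBImage::otsu(frame / 65535) * 65535
  for (i in 1:20) {
    lo <- frame <= thr
    if (!any(lo) || all(lo)) break
    thr_new <- (mean(frame[lo]) + mean(frame[!lo])) / 2
    if (abs(thr_new - thr) < 1e-6 * max(1, thr)) break
    thr <- thr_new
  }
  mask <- frame > thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  biggest <- which.max(counts)
  mask <- lab == biggest
  mask <- EBImage::fillHull(mask) > 0
  mask
}

#' Fit the moment-equivalent ellipse of a binary mask
#'
#' Axis lengths are `4 * sqrt(eigenvalues)` of the covariance matrix of
#' the foreground pixel coordinates — the ellipse with the same second
#' central moments as the mask. A `1/12` term (the variance of a unit
#' pixel) is added to each coordinate variance so that pixelated masks of
#' continuous shapes are measured without the point-sampling bias.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return List of class `ellipse_fit`: `centroid` (x, y in px, x along
#'   columns), `major_axis`, `minor_axis` (px), `orientation` (radians,
#'   major axis from the x-axis, in `[-pi/2, pi/2)`), `area` (px^2).
#' @export
fit_ellipse <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  x <- idx[, 2L]  # column = x
  y <- idx[, 1L]  # row = y
  cx <- mean(x); cy <- mean(y)
  n <- length(x)
  vxx <- sum((x - cx)^2) / n
  vyy <- sum((y - cy)^2) / n
  vxy <- sum((x - cx) * (y - cy)) / n
  # collinearity is judged on the raw moments, before the pixel-variance
  # correction below would hide it
  if (min(eigen(matrix(c(vxx, vxy, vxy, vyy), 2L),
                symmetric = TRUE, only.values = TRUE)$values) <= 1e-9) {
    stop("degenerate (collinear) mask")
  }
  cov <- matrix(c(vxx + 1 / 12, vxy, vxy, vyy + 1 / 12), 2L)
  e <- eigen(cov, symmetric = TRUE)
  v1 <- e$vectors[, 1L]
  ori <- atan2(v1[2L], v1[1L])
  if (ori >= pi / 2) ori <- ori - pi
  if (ori < -pi / 2) ori <- ori + pi
  structure(list(centroid = c(x = cx, y = cy),
                 major_axis = 4 * sqrt(e$values[1L]),
                 minor_axis = 4 * sqrt(e$values[2L]),
                 orientation = ori,
                 area = n),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> axes %.1f x %.1f px at (%.1f, %.1f), orientation %.2f rad\n",
    x$major_axis, x$minor_axis, x$centroid[1], x$centroid[2], x$orientation))
  invisible(x)
}

#' Compute the body-column width trace of a movie
#'
#' Segments each frame ([segment_body()]) and fits the moment ellipse
#' ([fit_ellipse()]); the minor axis is the body-column width, the major
#' axis the length. Frames with no usable foreground are linearly
#' interpolated from their neighbours when isolated (single invalid frame
#' between valid ones) and left invalid otherwise. More than 20% invalid
#' frames is an error.
#'
#' @param stack Movie array from [read_stack()] / [render_movie()].
#' @param frame_rate Acquisition rate, Hz (0.5 Hz in the width assay).
#' @return List of class `width_trace`: `times` (s), `width`, `length`
#'   (px), `valid` (logical; `FALSE` marks frames left invalid),
#'   `frame_rate`.
#' @export
compute_width_trace <- function(stack, frame_rate) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  n <- dim(stack)[3L]
  width <- rep(NA_real_, n)
  len <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mask <- segment_body(stack[, , i])
    if (!is.null(mask)) {
      fit <- fit_ellipse(mask)
      width[i] <- fit$minor_axis
      len[i] <- fit$major_axis
    }
  }
  bad <- is.na(width)
  if (mean(bad) > 0.2) {
    stop(sprintf("%.0f%% of frames could not be segmented", 100 * mean(bad)))
  }
  # interpolate isolated invalid frames
  for (i in which(bad)) {
    if (i > 1L && i < n && !bad[i - 1L] && !bad[i + 1L]) {
      width[i] <- (width[i - 1L] + width[i + 1L]) / 2
      len[i] <- (len[i - 1L] + len[i + 1L]) / 2
      bad[i] <- FALSE
    }
  }
  structure(list(times = (seq_len(n) - 1) / frame_rate,
                 width = width, length = len,
                 valid = !bad, frame_rate = frame_rate),
            class = "width_trace")
}

#' @export
print.width_trace <- function(x, ...) {
  cat(sprintf("<width_trace> %d frames at %g Hz, width %.1f-%.1f px\n",
              length(x$times), x$frame_rate,
              min(x$width, na.rm = TRUE), max(x$width, na.rm = TRUE)))
  invisible(x)
}

#' Detect contraction-elongation cycles from a width trace
#'
#' Local minima of the width trace with at least the stated prominence,
#' separated by at least `min_period`, mark the end of each elongation;
#' their mean is the average end-of-elongation width of the recording.
#'
#' @param wt A `width_trace`.
#' @param min_period Minimum spacing between cycle minima, seconds.
#' @param prominence Minimum prominence of a minimum, px; default 5% of
#'   the width range.
#' @return List of class `cycle_set`: `minima_times`, `minima_widths`,
#'   `mean_end_elongation_width` (`NA` when no minimum is found).
#' @export
detect_cycles <- function(wt, min_period = 60, prominence = NULL) {
  stopifnot(inherits(wt, "width_trace"))
  w <- wt$width
  if (anyNA(w)) {
    w <- stats::approx(wt$times[wt$valid], w[wt$valid], xout = wt$times,
                       rule = 2)$y
  }
  if (is.null(prominence)) prominence <- 0.05 * diff(range(w))
  y <- -w
  peaks <- local_maxima(y)
  out <- list(minima_times = numeric(0), minima_widths = numeric(0),
              mean_end_elongation_width = NA_real_)
  if (length(peaks) > 0) {
    prom <- peak_prominence(y, peaks)
    keep <- prom >= prominence
    peaks <- peaks[keep]
    prom <- prom[keep]
    if (length(peaks) > 0) {
      min_gap <- min_period * wt$frame_rate
      ord <- order(-prom, peaks)
      kept_pos <- numeric(0)
      kept <- logical(length(peaks))
      for (i in ord) {
        if (all(abs(peaks[i] - kept_pos) >= min_gap)) {
          kept[i] <- TRUE
          kept_pos <- c(kept_pos, peaks[i])
        }
      }
      sel <- sort(peaks[kept])
      out$minima_times <- wt$times[sel]
      out$minima_widths <- w[sel]
      out$mean_end_elongation_width <- mean(w[sel])
    }
  }
  structure(out, class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("<cycle_set> %d cycle minima, mean end-of-elongation width %.2f px\n",
              length(x$minima_times), x$mean_end_elongation_width))
  invisible(x)
}

#' Count body contractions from the length channel
#'
#' Automated surrogate for manual contraction scoring: a contraction is an
#' excursion in which body length falls below
#' `(1 - shortening_fraction)` times the preceding local maximum and then
#' recovers above that level.
#'
#' @param wt A `width_trace` (its `length` channel is used).
#' @param shortening_fraction Fractional shortening that counts as a
#'   contraction (default 0.3, i.e. a 30% length drop).
#' @return Integer contraction count.
#' @export
count_contractions <- function(wt, shortening_fraction = 0.3) {
  stopifnot(inherits(wt, "width_trace"),
            shortening_fraction > 0, shortening_fraction < 1)
  len <- wt$length
  if (anyNA(len)) {
    len <- stats::approx(wt$times[wt$valid], len[wt$valid], xout = wt$times,
                         rule = 2)$y
  }
  count <- 0L
  ref <- len[1L]
  contracted <- FALSE
  for (v in len[-1L]) {
    if (!contracted) {
      if (v > ref) ref <- v
      if (v < (1 - shortening_fraction) * ref) {
        count <- count + 1L
        contracted <- TRUE
      }
    } else if (v >= (1 - shortening_fraction) * ref) {
      contracted <- FALSE
      ref <- v
    }
  }
  count
}
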