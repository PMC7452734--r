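#' Normalise a raw trace to dF/F
#'
#' Computes `dF/F = (F - F0) / F0` with the baseline `F0` a running low
#' percentile (default 10th) of the raw trace over a sliding
#' `baseline_window`. A percentile baseline tracks photobleaching and
#' other drifts slower than the window while ignoring the sparse positive
#' calcium transients riding on top. For speed the percentile is
#' evaluated on a coarse grid (one evaluation per ~1/20 window) and
#' linearly interpolated; at the defaults this is indistinguishable from
#' the dense evaluation.
#'
#' @param trace A raw-units [fluor_trace].
#' @param baseline_window Window length in seconds; must span at least 10
#'   frames.
#' @param baseline_quantile Percentile used as the baseline (0-1).
#' @return A `fluor_trace` with `units = "dff"`.
#' @export
normalize_trace <- function(trace, baseline_window = 120,
                            baseline_quantile = 0.10) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (identical(trace$units, "dff")) stop("trace is already dF/F")
  fr <- trace$frame_rate
  if (baseline_window < 10 / fr) {
    stop("baseline_window must span at least 10 frames")
  }
  x <- trace$values
  n <- length(x)
  hw <- max(1L, round(baseline_window * fr / 2))
  stride <- max(1L, floor(hw / 10))
  centers <- unique(c(seq(1L, n, by = stride), n))
  f0c <- vapply(centers, function(i) {
    stats::quantile(x[max(1L, i - hw):min(n, i + hw)],
                    baseline_quantile, names = FALSE)
  }, numeric(1))
  f0 <- if (length(centers) > 1L) {
    stats::approx(centers, f0c, xout = seq_len(n), rule = 2)$y
  } else {
    rep(f0c, n)
  }
  if (any(f0 <= 0)) stop("baseline estimate non-positive; corrupt trace")
  out <- fluor_trace((x - f0) / f0, fr, units = "dff",
                     metadata = trace$metadata)
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  out
}

# indices of local maxima: y[i] > y[i-1] and y[i] >= y[i+1]
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  d <- diff(y)
  which(d[-(n - 1L)] > 0 & d[-1L] <= 0) + 1L
}

# topographic prominence of each peak: height above the higher of the two
# key saddles (lowest point between the peak and the nearest higher ground
# on each side; trace ends count as higher ground at the running minimum)
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(p) {
    h <- y[p]
    lmin <- h
    j <- p - 1L
    while (j >= 1L && y[j] <= h) {
      if (y[j] < lmin) lmin <- y[j]
      j <- j - 1L
    }
    rmin <- h
    j <- p + 1L
    while (j <= n && y[j] <= h) {
      if (y[j] < rmin) rmin <- y[j]
      j <- j + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# width of a peak at half its prominence, in samples (linear interpolation
# at the crossings)
half_prominence_width <- function(y, p, prom) {
  href <- y[p] - prom / 2
  n <- length(y)
  j <- p
  while (j > 1L && y[j - 1L] > href) j <- j - 1L
  left <- if (j == 1L) 1 else {
    (j - 1L) + (y[j - 1L] - href) / (y[j - 1L] - y[j])
  }
  k <- p
  while (k < n && y[k + 1L] > href) k <- k + 1L
  right <- if (k == n) n else {
    k + (y[k] - href) / (y[k] - y[k + 1L])
  }
  right - left
}

#' Estimate the noise SD of a trace robustly
#'
#' Estimates the SD of the sensor noise in an *unsmoothed* trace, and
#' optionally the SD that noise retains after boxcar smoothing over
#' `smooth_w` samples (white noise shrinks by `sqrt(smooth_w)`).
#'
#' The default `"psd"` method takes the median periodogram ordinate over
#' the top frequency band (0.4-0.5 cycles/sample, where for white noise
#' the periodogram is flat at the noise variance; the median is corrected
#' for the exponential distribution of periodogram ordinates). Calcium
#' transients are slow — at 2 Hz sampling a GCaMP6s-like kernel has
#' little power near the Nyquist frequency, and the median ignores the
#' sparse spectral lines of regular intra-burst pulse trains — so the
#' estimate is essentially unaffected by event rate, which matters in
#' contraction-rich recordings where transients can occupy most of the
#' trace and defeat any time-domain robust scale.
#' The `"diff_quantile"` method is the time-domain alternative: a low
#' quantile (default 0.2) of the absolute deviations of the first
#' differences from their median, rescaled to be consistent for
#' Gaussian noise (`breakdown_quantile = 0.5` gives the classical
#' first-difference MAD estimator).
#'
#' @param y Numeric vector: the unsmoothed dF/F (or raw) trace.
#' @param smooth_w Boxcar width in samples whose smoothed-noise SD is
#'   wanted (1 = the noise SD of `y` itself).
#' @param method `"psd"` or `"diff_quantile"`.
#' @param breakdown_quantile Quantile used by `"diff_quantile"`; the
#'   estimator tolerates up to `1 - breakdown_quantile` contaminated
#'   samples.
#' @return Estimated noise SD.
#' @export
estimate_noise_sd <- function(y, smooth_w = 1L,
                              method = c("psd", "diff_quantile"),
                              breakdown_quantile = 0.2) {
  method <- match.arg(method)
  n <- length(y)
  if (method == "psd" && n >= 64L) {
    pgram <- Mod(stats::fft(y - mean(y)))^2 / n
    # element j corresponds to frequency (j - 1) / n cycles per sample;
    # periodogram ordinates of white noise are sigma^2 * Exp(1), whose
    # median is sigma^2 * log(2)
    jlo <- floor(0.40 * n) + 1L
    jhi <- floor(0.50 * n) + 1L
    sigma <- sqrt(stats::median(pgram[jlo:jhi]) / log(2))
  } else {
    d <- diff(y)
    sigma <- stats::quantile(abs(d - stats::median(d)), breakdown_quantile,
                             names = FALSE) /
      stats::qnorm(0.5 + breakdown_quantile / 2) / sqrt(2)
  }
  sigma / sqrt(smooth_w)
}

boxcar_smooth <- function(y, w) {
  if (w <= 1L) return(y)
  k <- rep(1 / w, w)
  ys <- stats::filter(y, k, sides = 2)
  # shrink the window at the edges instead of dropping samples
  half <- (w - 1L) %/% 2L
  n <- length(y)
  for (i in seq_len(half)) {
    ys[i] <- mean(y[1L:(i + half)])
    ys[n - i + 1L] <- mean(y[(n - i + 1L - half):n])
  }
  as.numeric(ys)
}

# one detection pass: prominent local maxima with min-separation pruning
# (smaller peaks of a close pair dropped first, ties broken by position);
# thr may be per-sample (indexed at the peak position)
detect_pass <- function(ys, thr, min_gap) {
  peaks <- local_maxima(ys)
  if (length(peaks) == 0L) {
    return(list(peaks = integer(0), prom = numeric(0)))
  }
  prom <- peak_prominence(ys, peaks)
  thr_at <- if (length(thr) > 1L) thr[peaks] else thr
  keep <- prom >= thr_at & prom > 0
  peaks <- peaks[keep]
  prom <- prom[keep]
  if (length(peaks) > 1L) {
    ord <- order(-prom, peaks)
    kept <- logical(length(peaks))
    kept_pos <- numeric(0)
    for (i in ord) {
      if (all(abs(peaks[i] - kept_pos) >= min_gap)) {
        kept[i] <- TRUE
        kept_pos <- c(kept_pos, peaks[i])
      }
    }
    peaks <- peaks[kept]
    prom <- prom[kept]
  }
  list(peaks = peaks, prom = prom)
}

#' Detect calcium pulses in a dF/F trace
#'
#' Finds local maxima of the (lightly smoothed) trace whose topographic
#' prominence exceeds `threshold_k` times the robust noise SD, keeping
#' only peaks separated by at least `min_separation` (smaller peaks are
#' dropped first). The noise SD is estimated spectrally
#' ([estimate_noise_sd()]) from the top frequency band of the unsmoothed
#' trace, which keeps the threshold calibrated even when transients
#' occupy most of the recording; on long recordings it is estimated per
#' ~5-min block and interpolated, so the threshold also tracks slow
#' changes in the noise scale (e.g. residual additive drifts that dilute
#' dF/F locally). The reported pulse time is refined to the
#' raw-trace maximum within the smoothing window around each smoothed
#' peak, so the short pre-smoothing (which buys the detectability of the
#' small RP1 pulses at realistic noise) does not bias pulse times.
#' Amplitude is the raw dF/F at the refined peak; prominence and
#' half-prominence width are measured on the smoothed trace. Classes are
#' left `"unassigned"`; see [classify_pulses()].
#'
#' @param trace A dF/F [fluor_trace] from [normalize_trace()].
#' @param threshold_k Prominence threshold in units of noise SD.
#' @param min_separation Minimum peak separation, seconds; must be at
#'   least one frame interval.
#' @param smooth_s Boxcar pre-smoothing length, seconds (rounded to an odd
#'   number of samples; values below one frame disable smoothing).
#' @return A data.frame of class `pulse_set` with columns `time` (s),
#'   `amplitude`, `prominence`, `width_s`, `class`, and attributes
#'   `frame_rate`, `duration`, `noise_sd`, `threshold`.
#' @export
detect_pulses <- function(trace, threshold_k = 4, min_separation = 2,
                          smooth_s = 1.5) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (!identical(trace$units, "dff")) {
    stop("detect_pulses expects a dF/F trace; run normalize_trace() first")
  }
  fr <- trace$frame_rate
  if (min_separation < 1 / fr) {
    stop("min_separation must be at least one frame interval (1/frame_rate)")
  }
  y <- trace$values
  n <- length(y)
  w <- max(1L, as.integer(round(smooth_s * fr)))
  if (w %% 2L == 0L) w <- w + 1L
  ys <- boxcar_smooth(y, w)
  min_gap <- min_separation * fr

  # blockwise noise scale (~5-min blocks, >= 256 samples), interpolated
  block <- max(256L, as.integer(round(300 * fr)))
  n_blocks <- max(1L, n %/% block)
  if (n_blocks > 1L) {
    edges <- floor(seq(0L, n, length.out = n_blocks + 1L))
    centers <- (edges[-1] + edges[-length(edges)] + 1) / 2
    sig_b <- vapply(seq_len(n_blocks), function(b) {
      estimate_noise_sd(y[(edges[b] + 1L):edges[b + 1L]], smooth_w = w)
    }, numeric(1))
    sigma_t <- stats::approx(centers, sig_b, xout = seq_len(n),
                             rule = 2)$y
    sigma <- mean(sig_b)
  } else {
    sigma <- estimate_noise_sd(y, smooth_w = w)
    sigma_t <- rep(sigma, n)
  }
  thr <- threshold_k * sigma
  res <- detect_pass(ys, threshold_k * sigma_t, min_gap)
  peaks <- res$peaks
  prom <- res$prom

  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      prominence = numeric(0), width_s = numeric(0),
                      class = character(0))
  if (length(peaks) == 0L) {
    return(pulse_set(empty, fr, n / fr, sigma, thr))
  }

  # refine peak position and amplitude on the raw trace
  half <- (w - 1L) %/% 2L + 1L
  ref <- vapply(peaks, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    lo + which.max(y[lo:hi]) - 1L
  }, integer(1))
  widths <- vapply(seq_along(peaks), function(i) {
    half_prominence_width(ys, peaks[i], prom[i]) / fr
  }, numeric(1))

  df <- data.frame(time = (ref - 1L) / fr,
                   amplitude = y[ref],
                   prominence = prom,
                   width_s = widths,
                   class = rep("unassigned", length(peaks)))
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  pulse_set(df, fr, n / fr, sigma, thr)
}

pulse_set <- function(df, frame_rate, duration, noise_sd, threshold) {
  structure(df, class = c("pulse_set", "data.frame"),
            frame_rate = frame_rate, duration = duration,
            noise_sd = noise_sd, threshold = threshold)
}

#' Group pulses into bursts by inter-pulse interval
#'
#' Maximal runs of time-sorted pulses whose consecutive gaps are all at
#' most `max_ipi` and which contain at least `min_pulses` members become
#' bursts. Burst onset/offset are the first/last member pulse time,
#' optionally padded by `pad` seconds on each side.
#'
#' @param pulses A `pulse_set` from [detect_pulses()] (or any data.frame
#'   with a `time` column, time-sorted).
#' @param max_ipi Maximum intra-burst inter-pulse interval, seconds.
#' @param min_pulses Minimum pulses per burst.
#' @param pad Padding added to each side of the burst window, seconds.
#' @return A data.frame of class `burst_set` with columns `onset`,
#'   `offset`, `n_pulses`, `duration`, `intra_burst_frequency`
#'   (pulses/min), and attribute `pulse_burst`: an integer vector mapping
#'   each input pulse to its burst id (`NA` = outside any burst).
#' @export
group_bursts <- function(pulses, max_ipi = 10, min_pulses = 3, pad = 0) {
  times <- pulses$time
  m <- length(times)
  assign_id <- rep(NA_integer_, m)
  rows <- list()
  if (m > 0) {
    if (is.unsorted(times)) stop("pulses must be time-sorted")
    run_start <- 1L
    bid <- 0L
    flush <- function(i0, i1) {
      if (i1 - i0 + 1L >= min_pulses) {
        bid <<- bid + 1L
        assign_id[i0:i1] <<- bid
        rows[[bid]] <<- c(onset = times[i0] - pad,
                          offset = times[i1] + pad,
                          n_pulses = i1 - i0 + 1L)
      }
    }
    if (m > 1) {
      for (i in 2:m) {
        if (times[i] - times[i - 1L] > max_ipi) {
          flush(run_start, i - 1L)
          run_start <- i
        }
      }
    }
    flush(run_start, m)
  }
  if (length(rows) > 0) {
    df <- as.data.frame(do.call(rbind, rows))
    df$duration <- df$offset - df$onset
    df$intra_burst_frequency <- ifelse(df$duration > 0,
                                       df$n_pulses / df$duration * 60, NA_real_)
  } else {
    df <- data.frame(onset = numeric(0), offset = numeric(0),
                     n_pulses = integer(0), duration = numeric(0),
                     intra_burst_frequency = numeric(0))
  }
  structure(df, class = c("burst_set", "data.frame"),
            pulse_burst = assign_id, min_pulses = min_pulses)
}

#' Classify detected pulses as CB or RP1
#'
#' Pulses inside any burst are CB. Isolated pulses are RP1 when their
#' amplitude is below `amplitude_ratio` times the median CB amplitude;
#' larger isolated pulses count as single-pulse CB events only when
#' `min_pulses = 1`, otherwise they are flagged `"unassigned"` (CB-like
#' outliers). For muscle recordings (`tissue` `"ectoderm"`/`"endoderm"`)
#' RP1 pulses do not exist, so every detected pulse is treated as a
#' CB candidate and the RP1 set is forced empty.
#'
#' When no burst exists to anchor the CB amplitude scale (neural traces
#' only), every isolated pulse is classified RP1.
#'
#' @param pulses A `pulse_set`.
#' @param bursts The `burst_set` computed from these pulses.
#' @param amplitude_ratio Isolated-pulse amplitude cut, as a fraction of
#'   the median CB amplitude.
#' @param tissue `"neuron"`, `"ectoderm"` or `"endoderm"`.
#' @param min_pulses The `min_pulses` used when grouping bursts.
#' @return The pulse data.frame with `class` filled in.
#' @export
classify_pulses <- function(pulses, bursts, amplitude_ratio = 0.7,
                            tissue = c("neuron", "ectoderm", "endoderm"),
                            min_pulses = attr(bursts, "min_pulses")) {
  tissue <- match.arg(tissue)
  if (is.null(min_pulses)) min_pulses <- 3
  ids <- attr(bursts, "pulse_burst")
  if (is.null(ids)) ids <- rep(NA_integer_, nrow(pulses))
  stopifnot(length(ids) == nrow(pulses))
  cls <- rep("unassigned", nrow(pulses))
  in_burst <- !is.na(ids)
  cls[in_burst] <- "CB"
  if (tissue != "neuron") {
    cls[] <- "CB"  # RP1 pulses are not present in muscle activity
  } else if (any(!in_burst)) {
    med_cb <- stats::median(pulses$amplitude[in_burst])
    cut <- if (is.na(med_cb)) Inf else amplitude_ratio * med_cb
    iso <- which(!in_burst)
    small <- pulses$amplitude[iso] < cut
    cls[iso[small]] <- "RP1"
    cls[iso[!small]] <- if (min_pulses <= 1) "CB" else "unassigned"
  }
  pulses$class <- cls
  pulses
}

#' Summarise classified pulses into per-recording activity metrics
#'
#' The six panel metrics reported per recording: CB pulse number, CB total
#' time (sum of burst durations), CB pulse frequency (CB pulses per minute
#' of burst time; 0 when there is no burst time), burst count, RP1 pulse
#' number, RP1 total time (sum of RP1 half-prominence widths) and RP1
#' frequency (RP1 pulses per hour of recording).
#'
#' @param pulses Classified pulse data.frame from [classify_pulses()].
#' @param bursts The corresponding `burst_set`.
#' @param recording_duration Recording length, seconds.
#' @return One-row data.frame of class `activity_summary` with columns
#'   `cb_pulse_number`, `burst_count`, `cb_total_time_s`,
#'   `cb_pulse_frequency_per_min`, `rp1_pulse_number`, `rp1_total_time_s`,
#'   `rp1_frequency_per_h`, `recording_duration_s`.
#' @export
summarize_events <- function(pulses, bursts, recording_duration) {
  if (!(is.numeric(recording_duration) && recording_duration > 0)) {
    stop("recording_duration must be > 0")
  }
  cb_n <- sum(pulses$class == "CB")
  rp1 <- pulses$class == "RP1"
  cb_total <- sum(bursts$duration)
  out <- data.frame(
    cb_pulse_number = cb_n,
    burst_count = nrow(bursts),
    cb_total_time_s = cb_total,
    cb_pulse_frequency_per_min = if (cb_total > 0) cb_n / cb_total * 60 else 0,
    rp1_pulse_number = sum(rp1),
    rp1_total_time_s = if (any(rp1)) sum(pulses$width_s[rp1]) else 0,
    rp1_frequency_per_h = sum(rp1) / recording_duration * 3600,
    recording_duration_s = recording_duration
  )
  class(out) <- c("activity_summary", "data.frame")
  out
}

#' Score detected pulses against ground truth
#'
#' Greedy one-to-one matching of detected to true pulse times within
#' `tolerance` seconds, closest pairs first (ties broken by earlier
#' detected time), then standard precision / recall / F1. With no
#' detections precision is 1 by convention; with no truth recall is 1;
#' F1 is 0 whenever either count is 0 and the other is not.
#'
#' @param detected A `pulse_set`, or a numeric vector of detected times.
#' @param truth A `ground_truth` object, or a numeric vector of true times.
#' @param tolerance Matching tolerance, seconds (> 0).
#' @return List with `precision`, `recall`, `f1`, `n_matched`,
#'   `n_detected`, `n_truth`, and `matches` (two-column matrix of matched
#'   detected/truth indices).
#' @export
score_detection <- function(detected, truth, tolerance = 1) {
  stopifnot(tolerance > 0)
  det <- if (is.numeric(detected)) detected else detected$time
  tru <- if (is.numeric(truth)) truth else truth$pulses$time
  nd <- length(det)
  nt <- length(tru)
  matches <- matrix(integer(0), ncol = 2,
                    dimnames = list(NULL, c("detected", "truth")))
  if (nd > 0 && nt > 0) {
    dmat <- abs(outer(det, tru, "-"))
    cand <- which(dmat <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand], det[cand[, 1L]])
      cand <- cand[ord, , drop = FALSE]
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1L]; j <- cand[r, 2L]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE
          used_t[j] <- TRUE
          matches <- rbind(matches, c(i, j))
        }
      }
    }
  }
  tp <- nrow(matches)
  precision <- if (nd == 0) 1 else tp / nd
  recall <- if (nt == 0) 1 else tp / nt
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1,
       n_matched = tp, n_detected = nd, n_truth = nt, matches = matches)
}

#' Run the full activity-detection pipeline on one trace
#'
#' Convenience wrapper: [normalize_trace()] (if the trace is raw) ->
#' [detect_pulses()] -> [group_bursts()] -> [classify_pulses()] ->
#' [summarize_events()].
#'
#' @param trace A [fluor_trace] (raw or dF/F).
#' @param tissue Tissue label; defaults to the trace metadata, else
#'   `"neuron"`.
#' @param baseline_window,threshold_k,min_separation,smooth_s,max_ipi,min_pulses,amplitude_ratio
#'   Detection knobs; see the stage functions.
#' @return List with `trace` (dF/F), `pulses`, `bursts`, `summary`.
#' @export
analyze_trace <- function(trace, tissue = NULL,
                          baseline_window = 120, threshold_k = 4,
                          min_separation = 2, smooth_s = 1.5,
                          max_ipi = 10, min_pulses = 3,
                          amplitude_ratio = 0.7) {
  if (is.null(tissue)) {
    tissue <- trace$metadata$tissue
    if (is.null(tissue)) tissue <- "neuron"
  }
  dff <- if (identical(trace$units, "dff")) {
    trace
  } else {
    normalize_trace(trace, baseline_window = baseline_window)
  }
  pulses <- detect_pulses(dff, threshold_k = threshold_k,
                          min_separation = min_separation,
                          smooth_s = smooth_s)
  bursts <- group_bursts(pulses, max_ipi = max_ipi, min_pulses = min_pulses)
  pulses <- classify_pulses(pulses, bursts, amplitude_ratio = amplitude_ratio,
                            tissue = tissue, min_pulses = min_pulses)
  duration <- length(dff$values) / dff$frame_rate
  list(trace = dff, pulses = pulses, bursts = bursts,
       summary = summarize_events(pulses, bursts, duration))
}
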