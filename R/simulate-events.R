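#' Simulate ground-truth CB and RP1 events
#'
#' Draws contraction-burst onsets as a homogeneous Poisson process at
#' `cb_burst_rate * osmolarity_multiplier` and fills each burst with a
#' shifted-Poisson pulse train (`1 + Poisson(pulses_per_burst_mean)` pulses
#' at `intra_burst_interval` spacing). An onset that would fall inside the
#' refractory span of the preceding burst is deferred to the end of that
#' span; deferral preserves the Poisson burst count while guaranteeing
#' non-overlapping burst windows. RP1 pulses are a jittered periodic
#' process at `rp1_rate`; any RP1 pulse falling inside a burst window
#' padded by `rp1_burst_margin` is discarded (elongation and contraction
#' programs are mutually exclusive).
#'
#' Pulse times mark the *peak* of the calcium transient; see
#' [render_trace()].
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `ground_truth`: a list with
#'   \describe{
#'     \item{pulses}{data.frame with columns `time` (s), `class`
#'       (`"CB"`/`"RP1"`) and `burst` (burst id, `NA` for RP1).}
#'     \item{burst_windows}{data.frame with columns `onset`, `offset` (s),
#'       the first/last pulse time of each burst.}
#'     \item{duration, frame_rate}{copied from the config.}
#'   }
#' @export
#' @examples
#' ev <- simulate_events(simulation_config(duration = 600, seed = 7))
#' nrow(ev$burst_windows)
simulate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_events_impl(config))
}

simulate_events_impl <- function(cfg) {
  dur <- cfg$duration
  ibi <- cfg$intra_burst_interval
  rate <- cfg$cb_burst_rate * cfg$osmolarity_multiplier / 3600  # per second

  pulse_time <- numeric(0)
  pulse_class <- character(0)
  pulse_burst <- integer(0)
  onset <- numeric(0)
  offset <- numeric(0)

  if (rate > 0) {
    n_bursts <- stats::rpois(1L, rate * dur)
    raw_onsets <- sort(stats::runif(n_bursts, 0, dur))
    prev_end <- -Inf
    bid <- 0L
    for (t0 in raw_onsets) {
      start <- max(t0, prev_end + cfg$refractory_gap)
      np <- 1L + stats::rpois(1L, cfg$pulses_per_burst_mean)
      times <- start + (seq_len(np) - 1L) * ibi
      times <- times[times < dur]
      if (length(times) == 0L) next
      bid <- bid + 1L
      pulse_time <- c(pulse_time, times)
      pulse_class <- c(pulse_class, rep("CB", length(times)))
      pulse_burst <- c(pulse_burst, rep(bid, length(times)))
      onset <- c(onset, times[1L])
      offset <- c(offset, times[length(times)])
      prev_end <- start + (np - 1L) * ibi  # full nominal span, even if clipped
    }
  }

  if (cfg$rp1_rate > 0) {
    period <- 3600 / cfg$rp1_rate
    phase <- stats::runif(1L, 0, period)
    k <- 0:ceiling(dur / period)
    rp1 <- phase + k * period +
      stats::rnorm(length(k), 0, cfg$rp1_jitter_frac * period)
    rp1 <- sort(rp1[rp1 > 0 & rp1 < dur])
    if (length(onset) > 0 && length(rp1) > 0) {
      lo <- onset - cfg$rp1_burst_margin
      hi <- offset + cfg$rp1_burst_margin
      inside <- vapply(rp1, function(t) any(t >= lo & t <= hi), logical(1))
      rp1 <- rp1[!inside]
    }
    pulse_time <- c(pulse_time, rp1)
    pulse_class <- c(pulse_class, rep("RP1", length(rp1)))
    pulse_burst <- c(pulse_burst, rep(NA_integer_, length(rp1)))
  }

  ord <- order(pulse_time)
  structure(list(
    pulses = data.frame(time = pulse_time[ord],
                        class = pulse_class[ord],
                        burst = pulse_burst[ord]),
    burst_windows = data.frame(onset = onset, offset = offset),
    duration = dur,
    frame_rate = cfg$frame_rate
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d bursts, %d CB + %d RP1 pulses over %.0f s\n",
              nrow(x$burst_windows),
              sum(x$pulses$class == "CB"),
              sum(x$pulses$class == "RP1"),
              x$duration))
  invisible(x)
}

#' Write / read ground-truth events as a JSON sidecar
#'
#' @param events A `ground_truth` object.
#' @param path Output JSON path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns a `ground_truth` object.
#' @export
write_ground_truth <- function(events, path) {
  stopifnot(inherits(events, "ground_truth"))
  jsonlite::write_json(
    list(duration = events$duration, frame_rate = events$frame_rate,
         pulses = events$pulses, burst_windows = events$burst_windows),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pulses <- as.data.frame(x$pulses)
  if (nrow(pulses) == 0) {
    pulses <- data.frame(time = numeric(0), class = character(0),
                         burst = integer(0))
  }
  bw <- as.data.frame(x$burst_windows)
  if (nrow(bw) == 0) bw <- data.frame(onset = numeric(0), offset = numeric(0))
  structure(list(pulses = pulses, burst_windows = bw,
                 duration = x$duration, frame_rate = x$frame_rate),
            class = "ground_truth")
}
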