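#' Calcium transient kernel
#'
#' Difference-of-exponentials impulse response
#' `k(u) = (exp(-u/decay_tau) - exp(-u/rise_tau)) / K` for `u >= 0`,
#' normalised so its maximum is 1, and shifted so the maximum falls at
#' `u = 0` when evaluated through [render_trace()] (pulse times mark the
#' transient peak). `calcium_kernel()` evaluates the unshifted kernel;
#' `kernel_peak_time()` returns the lag of the peak after kernel onset,
#' `rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)`.
#'
#' @param u Time since kernel onset, seconds (values < 0 give 0).
#' @param rise_tau,decay_tau Time constants, seconds; `decay_tau > rise_tau`.
#' @return Kernel values (unit peak) / the peak lag in seconds.
#' @export
#' @examples
#' tp <- kernel_peak_time(0.3, 1.5)
#' calcium_kernel(tp, 0.3, 1.5)  # 1 by construction
calcium_kernel <- function(u, rise_tau = 0.3, decay_tau = 1.5) {
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  tp <- kernel_peak_time(rise_tau, decay_tau)
  K <- exp(-tp / decay_tau) - exp(-tp / rise_tau)
  out <- numeric(length(u))
  pos <- u >= 0
  out[pos] <- (exp(-u[pos] / decay_tau) - exp(-u[pos] / rise_tau)) / K
  out
}

#' @rdname calcium_kernel
#' @export
kernel_peak_time <- function(rise_tau = 0.3, decay_tau = 1.5) {
  stopifnot(decay_tau > rise_tau, rise_tau > 0)
  rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
}

#' Render a fluorescence trace from ground-truth events
#'
#' Samples
#' `F(t) = baseline * exp(-t / bleach_tau) * (1 + signal(t) + eps(t))`
#' at `frame_rate`, where `signal(t)` is the sum over pulses of the
#' peak-normalised calcium kernel scaled by the class amplitude and
#' aligned so each kernel peaks at its pulse time, and `eps` is Gaussian
#' noise with SD `noise_sd`. Because the noise multiplies the bleaching
#' baseline, `noise_sd` is exactly the noise SD in dF/F units.
#'
#' @param events A `ground_truth` object from [simulate_events()].
#' @param config The [simulation_config()] the events were generated with.
#' @return A [fluor_trace] in raw units, with the events attached as
#'   attribute `"ground_truth"`.
#' @export
render_trace <- function(events, config) {
  stopifnot(inherits(events, "ground_truth"), inherits(config, "sim_config"))
  if (nrow(events$pulses) > 0 &&
      (min(events$pulses$time) < 0 || max(events$pulses$time) > config$duration)) {
    stop("events lie outside [0, duration]")
  }
  n <- round(config$duration * config$frame_rate)
  fr <- config$frame_rate
  t <- (seq_len(n) - 1) / fr
  tp <- kernel_peak_time(config$rise_tau, config$decay_tau)

  signal <- numeric(n)
  if (nrow(events$pulses) > 0) {
    amps <- ifelse(events$pulses$class == "CB",
                   config$cb_amplitude, config$rp1_amplitude)
    span <- 8 * config$decay_tau
    for (i in seq_len(nrow(events$pulses))) {
      pt <- events$pulses$time[i]
      i0 <- max(1L, ceiling((pt - tp) * fr) + 1L)
      i1 <- min(n, floor((pt - tp + span) * fr) + 1L)
      if (i0 > i1) next
      idx <- i0:i1
      signal[idx] <- signal[idx] +
        amps[i] * calcium_kernel(t[idx] - pt + tp,
                                 config$rise_tau, config$decay_tau)
    }
  }

  eps <- if (config$noise_sd > 0) {
    withr::with_seed(config$seed + 1L, stats::rnorm(n, 0, config$noise_sd))
  } else {
    numeric(n)
  }
  bleach <- if (is.finite(config$bleach_tau)) {
    exp(-t / config$bleach_tau)
  } else {
    rep(1, n)
  }
  values <- config$baseline * bleach * (1 + signal + eps)

  tr <- fluor_trace(values, fr, units = "raw",
                    metadata = list(condition = config$condition_label,
                                    tissue = config$tissue,
                                    source = "synthetic"))
  attr(tr, "ground_truth") <- events
  tr
}
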