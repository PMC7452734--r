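# shared fixtures and independent oracles (built in code at test time)

# slow-cycle configuration used for width-assay simulations: the width
# experiment images at 0.5 Hz with minutes-scale contraction cycles
width_assay_config <- function(seed = 1, duration = 1800, ...) {
  args <- utils::modifyList(
    list(duration = duration, seed = seed, cb_burst_rate = 20,
         refractory_gap = 90, elongation_tau = 45),
    list(...))
  do.call(simulation_config, args)
}

# single-frame trajectory for rendering standalone ellipses
static_trajectory <- function(length_px, width_px) {
  structure(list(times = 0, length = length_px, width = width_px,
                 centroid = matrix(0, 1, 2), frame_rate = 1),
            class = "geometry_trajectory")
}

render_ellipse_frame <- function(length_px, width_px, orientation = 0,
                                 frame_px = max(44, ceiling(length_px) + 12),
                                 intensity = 200) {
  st <- render_movie(static_trajectory(length_px, width_px), NULL,
                     frame_shape = c(frame_px, frame_px),
                     orientation = orientation, intensity_scale = intensity)
  st[, , 1]
}

# brute-force peak scan: every sample greater than both neighbours with
# prominence above threshold (the oracle detector for noiseless traces)
brute_force_peaks <- function(y, thr) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  keep <- vapply(idx, function(p) {
    h <- y[p]
    lmin <- h; j <- p - 1L
    while (j >= 1L && y[j] <= h) { lmin <- min(lmin, y[j]); j <- j - 1L }
    rmin <- h; j <- p + 1L
    while (j <= n && y[j] <= h) { rmin <- min(rmin, y[j]); j <- j + 1L }
    (h - max(lmin, rmin)) >= thr
  }, logical(1))
  idx[keep]
}

# permutation oracle for the pooled two-sample t test (two-tailed p).
# Under permutation the total sum of squares is fixed, and
# t^2 = (n-2) SSB / (SST - SSB) with SSB proportional to the squared
# deviation of the group-A sum from its expectation, so |t| is a
# monotone function of |sum(group A) - na * grand mean|: the p value
# can be computed from group sums alone.
permutation_t_p <- function(a, b, n_perm = 1e5, seed = 1) {
  x <- c(a, b)
  na <- length(a)
  n <- length(x)
  obs <- abs(sum(a) - na * mean(x))
  withr::with_seed(seed, {
    sums <- vapply(seq_len(n_perm),
                   function(i) sum(x[sample.int(n, na)]), numeric(1))
    mean(abs(sums - na * mean(x)) >= obs * (1 - 1e-12))
  })
}

# studentized-range CDF by direct numerical integration (independent of
# stats::ptukey): P(Q <= q) for k groups and df error degrees of freedom
ptukey_oracle <- function(q, k, df) {
  range_cdf <- function(r) {
    if (r <= 0) return(0)
    k * stats::integrate(function(z) {
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - r))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  s_density <- function(s) {
    exp(df / 2 * log(df) + (df - 1) * log(s) - df * s^2 / 2 -
          lgamma(df / 2) - (df / 2 - 1) * log(2))
  }
  stats::integrate(Vectorize(function(s) s_density(s) * range_cdf(q * s)),
                   0, Inf, rel.tol = 1e-8)$value
}
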