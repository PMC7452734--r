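#' Condition multipliers for the osmolarity experiment
#'
#' Dimensionless factors applied to the contraction-burst rate to emulate
#' the bidirectional effect of media osmolarity on CB activity: hypo-osmotic
#' media ("low", diH2O) speed the contraction cycle up, hyper-osmotic media
#' ("high", 50 mM sucrose) slow it down. The values are synthetic design
#' choices, not measurements.
#'
#' @return Named numeric vector with elements `low`, `control`, `high`.
#' @export
#' @examples
#' osmolarity_multipliers()
osmolarity_multipliers <- function() {
  c(low = 1.5, control = 1.0, high = 0.5)
}

#' Configuration for a synthetic Hydra recording
#'
#' Bundles every parameter of the synthetic-recording generator: the
#' recording geometry (duration, frame rate), the CB burst point process,
#' the RP1 quasi-periodic process, calcium-kernel kinetics, sensor noise
#' and photobleaching, and the contraction/elongation body geometry used
#' for width movies. Defaults emulate a 2-h whole-body GCaMP6s session
#' imaged at 2 Hz in a mounted preparation.
#'
#' @param duration Recording length in seconds.
#' @param frame_rate Acquisition rate of the activity movie, Hz.
#' @param cb_burst_rate Contraction-burst rate, bursts/hour, before the
#'   osmolarity multiplier is applied.
#' @param pulses_per_burst_mean Mean of the Poisson part of the per-burst
#'   pulse count; each burst carries `1 + Poisson(pulses_per_burst_mean)`
#'   pulses so a burst is never empty.
#' @param intra_burst_interval Spacing of pulses within a burst, seconds.
#' @param rp1_rate RP1 pulse rate, pulses/hour. Use 0 for muscle-like
#'   recordings (RP1 pulses are absent in muscle activity).
#' @param cb_amplitude,rp1_amplitude Peak dF/F of a single CB / RP1 pulse.
#' @param rise_tau,decay_tau Calcium-kernel time constants, seconds
#'   (GCaMP6s-like defaults). Must satisfy `decay_tau > rise_tau > 0`.
#' @param noise_sd Gaussian sensor noise SD in dF/F units.
#' @param bleach_tau Photobleaching time constant, seconds; `Inf` disables
#'   bleaching.
#' @param baseline Baseline fluorescence, arbitrary units.
#' @param condition_label One of `"low"`, `"control"`, `"high"`.
#' @param osmolarity_multiplier Dimensionless factor applied to
#'   `cb_burst_rate`; defaults to the value of [osmolarity_multipliers()]
#'   for `condition_label`.
#' @param tissue Tissue label: `"neuron"`, `"ectoderm"` or `"endoderm"`.
#' @param refractory_gap Minimum quiet gap after a burst before the next
#'   burst may start, seconds. Colliding Poisson onsets are deferred to the
#'   end of this gap, which preserves the Poisson burst count.
#' @param rp1_jitter_frac Gaussian jitter SD of RP1 pulse times, as a
#'   fraction of the RP1 period.
#' @param rp1_burst_margin Half-width of the RP1 exclusion zone around each
#'   burst window, seconds (contraction and elongation programs are
#'   mutually exclusive).
#' @param geometry_frame_rate Frame rate of the width movie, Hz (the width
#'   assay images at 0.5 Hz).
#' @param width_elongated,width_contracted Body-column width at full
#'   elongation / contraction, px.
#' @param length_elongated,length_contracted Body-column length at full
#'   elongation / contraction, px.
#' @param elongation_tau,contraction_tau Time constants of the relaxation
#'   towards the elongated / contracted posture, seconds.
#' @param seed Integer seed; identical config + seed reproduce identical
#'   output bit for bit.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_events()], [render_trace()], [simulate_geometry()]
#' @export
#' @examples
#' cfg <- simulation_config(duration = 600, condition_label = "high")
#' cfg$osmolarity_multiplier
simulation_config <- function(duration = 7200,
                              frame_rate = 2,
                              cb_burst_rate = 50,
                              pulses_per_burst_mean = 10,
                              intra_burst_interval = 2.5,
                              rp1_rate = 120,
                              cb_amplitude = 1.0,
                              rp1_amplitude = 0.4,
                              rise_tau = 0.3,
                              decay_tau = 1.5,
                              noise_sd = 0.08,
                              bleach_tau = 5400,
                              baseline = 100,
                              condition_label = "control",
                              osmolarity_multiplier = NULL,
                              tissue = "neuron",
                              refractory_gap = 15,
                              rp1_jitter_frac = 0.1,
                              rp1_burst_margin = 12,
                              geometry_frame_rate = 0.5,
                              width_elongated = 40,
                              width_contracted = 80,
                              length_elongated = 150,
                              length_contracted = 90,
                              elongation_tau = 60,
                              contraction_tau = 5,
                              seed = 1L) {
  condition_label <- match.arg(condition_label, c("control", "low", "high"))
  tissue <- match.arg(tissue, c("neuron", "ectoderm", "endoderm"))
  if (is.null(osmolarity_multiplier)) {
    osmolarity_multiplier <- unname(osmolarity_multipliers()[condition_label])
  }
  cfg <- list(
    duration = duration, frame_rate = frame_rate,
    cb_burst_rate = cb_burst_rate,
    pulses_per_burst_mean = pulses_per_burst_mean,
    intra_burst_interval = intra_burst_interval,
    rp1_rate = rp1_rate,
    cb_amplitude = cb_amplitude, rp1_amplitude = rp1_amplitude,
    rise_tau = rise_tau, decay_tau = decay_tau,
    noise_sd = noise_sd, bleach_tau = bleach_tau, baseline = baseline,
    condition_label = condition_label,
    osmolarity_multiplier = osmolarity_multiplier,
    tissue = tissue,
    refractory_gap = refractory_gap,
    rp1_jitter_frac = rp1_jitter_frac,
    rp1_burst_margin = rp1_burst_margin,
    geometry_frame_rate = geometry_frame_rate,
    width_elongated = width_elongated,
    width_contracted = width_contracted,
    length_elongated = length_elongated,
    length_contracted = length_contracted,
    elongation_tau = elongation_tau,
    contraction_tau = contraction_tau,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  chk(num1(cfg$duration) && cfg$duration > 0, "duration must be > 0")
  chk(num1(cfg$frame_rate) && cfg$frame_rate > 0, "frame_rate must be > 0")
  for (f in c("cb_burst_rate", "rp1_rate")) {
    chk(num1(cfg[[f]]) && is.finite(cfg[[f]]) && cfg[[f]] >= 0,
        paste(f, "must be finite and >= 0"))
  }
  chk(num1(cfg$osmolarity_multiplier) && is.finite(cfg$osmolarity_multiplier) &&
        cfg$osmolarity_multiplier >= 0,
      "osmolarity_multiplier must be finite and >= 0")
  chk(num1(cfg$rise_tau) && num1(cfg$decay_tau) &&
        cfg$decay_tau > cfg$rise_tau && cfg$rise_tau > 0,
      "must have decay_tau > rise_tau > 0")
  chk(num1(cfg$pulses_per_burst_mean) && cfg$pulses_per_burst_mean >= 0,
      "pulses_per_burst_mean must be >= 0")
  chk(num1(cfg$intra_burst_interval) && cfg$intra_burst_interval > 0,
      "intra_burst_interval must be > 0")
  chk(num1(cfg$noise_sd) && cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(num1(cfg$bleach_tau) && cfg$bleach_tau > 0,
      "bleach_tau must be > 0 (Inf disables bleaching)")
  chk(num1(cfg$baseline) && cfg$baseline > 0, "baseline must be > 0")
  chk(num1(cfg$refractory_gap) && cfg$refractory_gap >= 0,
      "refractory_gap must be >= 0")
  chk(num1(cfg$geometry_frame_rate) && cfg$geometry_frame_rate > 0,
      "geometry_frame_rate must be > 0")
  chk(all(vapply(cfg[c("width_elongated", "width_contracted",
                       "length_elongated", "length_contracted")],
                 function(x) num1(x) && x > 0, logical(1))),
      "geometry dimensions must be > 0")
  chk(cfg$width_contracted > cfg$width_elongated,
      "width_contracted must exceed width_elongated")
  chk(cfg$length_elongated > cfg$length_contracted,
      "length_elongated must exceed length_contracted")
  chk(num1(cfg$seed) && abs(cfg$seed) < 2^31, "seed must be a 32-bit integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %s recording, %.0f s at %g Hz (%s, multiplier %.2f)\n",
              x$tissue, x$duration, x$frame_rate,
              x$condition_label, x$osmolarity_multiplier))
  cat(sprintf("  CB: %.3g bursts/h, mean %.3g pulses/burst every %.3g s\n",
              x$cb_burst_rate, x$pulses_per_burst_mean + 1,
              x$intra_burst_interval))
  cat(sprintf("  RP1: %.3g pulses/h | noise SD %.3g dF/F | bleach tau %.3g s\n",
              x$rp1_rate, x$noise_sd, x$bleach_tau))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file holds a mapping whose keys mirror the arguments of
#' [simulation_config()]; missing keys fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, vals)
}
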