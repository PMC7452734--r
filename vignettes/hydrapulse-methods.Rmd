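---
title: "Methods: whole-body calcium activity and body-width analysis in Hydra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body calcium activity and body-width analysis in Hydra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific background

*Hydra vulgaris* shows a small repertoire of stereotyped behaviours, the
most prominent being spontaneous longitudinal contractions. In whole-body
GCaMP recordings these appear as **contraction bursts (CB)**: clusters of
large calcium pulses, synchronous across the CB neuronal circuit and the
ectodermal muscle, coinciding with each body contraction. A second
ectodermal circuit, **RP1 (rhythmic potential 1)**, fires smaller,
isolated, quasi-periodic pulses associated with body elongation; RP1
activity is a neuronal signature and is absent from muscle recordings.
Media osmolarity modulates this system bidirectionally: hypo-osmotic
media speed the contraction cycle up and hyper-osmotic media slow it
down, and the body column is correspondingly wider (control) or narrower
(hyper-osmotic) at the end of each elongation.

`hydrapulse` implements the full analysis chain for such recordings:

1. **Trace extraction** — whole-body fluorescence per frame from a
   multi-page TIFF movie (`extract_whole_body_trace()`).
2. **Event detection** — dF/F normalisation, pulse detection, burst
   grouping, CB/RP1 classification, per-recording activity summaries
   (`normalize_trace()`, `detect_pulses()`, `group_bursts()`,
   `classify_pulses()`, `summarize_events()`; wrapped by
   `analyze_trace()`).
3. **Width morphometry** — per-frame segmentation, moment-based ellipse
   fit, contraction-cycle detection, end-of-elongation width
   (`segment_body()`, `fit_ellipse()`, `compute_width_trace()`,
   `detect_cycles()`, `count_contractions()`).
4. **Condition comparison** — mean ± SEM, two-tailed unpaired Student's
   t, one-way ANOVA with Tukey's multiple comparison test
   (`group_summary()`, `t_test_unpaired()`, `anova_tukey()`,
   `build_report()`).
5. **Synthetic recordings** — a ground-truthed generator of traces and
   movies with osmolarity-dependent burst rates
   (`simulation_config()`, `simulate_events()`, `render_trace()`,
   `simulate_geometry()`, `render_movie()`), used to validate every
   stage end to end. `run_experiment()` chains all of it into a
   reproducible three-condition experiment.

No public recordings of this kind exist, so the package's tests and its
acceptance script validate the pipeline entirely against the generator,
whose statistical structure is described next.

## The synthetic-recording generator

### Event model

CB burst onsets are a homogeneous Poisson process at
`cb_burst_rate * osmolarity_multiplier` (bursts/hour). Each burst carries
`1 + Poisson(pulses_per_burst_mean)` pulses at `intra_burst_interval`
spacing, so a burst is never empty. Two bursts cannot overlap
physically, so an onset falling inside the span of the preceding burst
plus a `refractory_gap` is *deferred* to the end of that span. Deferral,
rather than discarding, keeps the expected burst count exactly
`rate x duration` (the Poisson expectation the unit tests assert) while
guaranteeing that consecutive bursts are separated by at least the
refractory gap — which also makes ground-truth and detected burst counts
directly comparable, because the gap exceeds the burst-grouping
`max_ipi`.

RP1 pulses are a jittered periodic process (period `3600 / rp1_rate` s,
Gaussian jitter with SD `rp1_jitter_frac` of the period), reflecting the
oscillatory firing of the elongation circuit, rather than a Poisson
process. RP1 pulses falling within `rp1_burst_margin` (12 s) of a burst
window are removed: contraction and elongation are mutually exclusive
motor programs, and the margin slightly exceeds `max_ipi` so the
generator never plants an RP1 pulse that an interval-based grouper would
be forced to absorb into a burst.

### Trace model

Pulse times mark the **peak** of the calcium transient. The rendered
trace is

```
F(t) = baseline * exp(-t / bleach_tau) * (1 + signal(t) + eps(t))
```

where `signal(t)` sums, over pulses, a difference-of-exponentials kernel
`exp(-u/decay_tau) - exp(-u/rise_tau)` normalised to unit peak, scaled
by the class amplitude, and aligned so each kernel maximum falls at its
pulse time; `eps` is white Gaussian noise with SD `noise_sd`. Because
noise multiplies the bleaching baseline (like photon noise), `noise_sd`
is exactly the noise SD in dF/F units at any point of the recording.
Peak-aligned timing makes the trace maximum of an isolated pulse
coincide with its ground-truth time, so detection scoring with a ±1 s
tolerance is well posed; with onset-aligned timing the kernel peak lag
(`rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau /
rise_tau)`, 0.60 s at the defaults) would consume most of that
tolerance.

### Default parameters and their justification

| parameter | default | rationale |
|---|---|---|
| `duration`, `frame_rate` | 7200 s, 2 Hz | 2-h activity sessions imaged at 2 Hz |
| `cb_burst_rate` | 50 /h | a contraction burst every ~70 s, in the classic range for mounted animals; see the calibration note below |
| `pulses_per_burst_mean` | 10 (mean 11 pulses/burst) | large bursts are the norm; per-recording CB pulse counts (~1100 per 2 h) are then on the scale reported for whole-body recordings |
| `intra_burst_interval` | 2.5 s | intra-burst pulse rates of ~0.4 Hz |
| `refractory_gap` | 15 s | posture recovery between bursts; > `max_ipi` |
| `rp1_rate` | 120 /h | a ~30-s RP period, with 10% jitter |
| `cb_amplitude`, `rp1_amplitude` | 1.0, 0.4 dF/F | RP1 pulses are visibly smaller than CB pulses; the ratio makes amplitude a usable secondary classification cue |
| `rise_tau`, `decay_tau` | 0.3 s, 1.5 s | GCaMP6s-like kinetics |
| `noise_sd` | 0.08 dF/F | signal-to-noise 5 for the *smallest* event class (RP1 amplitude 0.4 / 5); CB pulses then sit at SNR 12.5 |
| `bleach_tau` | 5400 s | ~25% intensity loss over a 2-h session |
| `osmolarity_multiplier` | low 1.5 / control 1.0 / high 0.5 | synthetic stand-ins for the bidirectional osmolarity effect; **design choices, not measurements** |

A calibration note on the CB rates: the paper behind this design reports
no numeric burst rates, so the defaults were fixed once by a power
analysis of the package's own benchmark experiment (three conditions,
n = 8 recordings of 600 s each). With Poisson burst counts and
shifted-Poisson burst sizes, the low-vs-high mean difference in CB pulse
number is `1.0 * rate * duration * mean_pulses` against a per-recording
SD of roughly `sqrt(rate * duration * E[N^2])`; rates much below
~40 bursts/h leave that comparison under-powered at 600 s, while the
chosen 50/h gives the Tukey low-vs-high comparison >95% power and makes
the three group means order correctly in essentially every replicate.
The rates remain configurable and all pipeline behaviour is independent
of them.

### Geometry and movies

Body posture follows a contraction envelope `c(t)` in `[0, 1]` that
relaxes towards 1 (contracted) with `contraction_tau` = 5 s inside burst
windows and towards 0 (elongated) with `elongation_tau` between them.
Width interpolates `width_elongated` (40 px) to `width_contracted`
(80 px) as `c` rises while length interpolates `length_elongated`
(150 px) down to `length_contracted` (90 px), so width and length are
anti-correlated by construction. `length_contracted` deliberately
exceeds `width_contracted`: a contracted animal remains slightly longer
than wide, and keeping the two axes separated avoids the major/minor
axis degeneracy of the moment ellipse during deep contraction. The
ground-truth end-of-elongation width is the minimum width in each
inter-contraction interval.

Movies draw a filled ellipse per frame (axes = length and width) with
interior intensity proportional to the fluorescence trace, with
supersampled fractional pixel coverage at the outline emulating optical
blur, written as uncompressed 16-bit multi-page TIFF.

Width-assay simulations in the tests and the acceptance script use a
slow-cycle configuration (`cb_burst_rate` 20/h, `refractory_gap` 90 s,
`elongation_tau` 45 s): the width experiment is a separate assay imaged
at 0.5 Hz with minutes-scale contraction cycles, and the long refractory
gap guarantees every inter-contraction interval exceeds
`detect_cycles()`'s default `min_period` of 60 s, so ground truth and
detection count the same cycles.

## Event detection

### dF/F normalisation

`normalize_trace()` computes `dF/F = (F - F0)/F0` with `F0` a running
10th percentile over a 120-s window (evaluated on a coarse grid, one
point per ~1/20 window, and linearly interpolated — indistinguishable
from the dense evaluation at these scales). A low-percentile baseline
tracks photobleaching and other drifts slower than the window while
ignoring the sparse, strictly positive calcium transients. The result
carries a small constant offset (the percentile sits below the noise
mean), which is irrelevant downstream because detection uses prominences
and classification uses amplitude *ratios*.

### Noise estimation

The detection threshold is `threshold_k` times the noise SD, so the
noise estimate is the linchpin. The classical robust choice — 1.4826
times the median absolute deviation of the first differences over
sqrt(2) — assumes that at most half the samples are contaminated by
signal. Contraction-rich recordings violate that badly: at the default
study conditions 30–70% of samples sit on transient slopes, the MAD
estimate inflates about two-fold, and recall collapses on the busiest
traces. Time-domain repairs (lower quantiles, iterative transient
masking) stayed duty-dependent in our testing.

`estimate_noise_sd()` therefore estimates the noise spectrally: the
median periodogram ordinate over the top frequency band (0.4–0.5
cycles/sample), corrected for the Exp(1) distribution of periodogram
ordinates of white noise (median = variance × log 2). Calcium kernels
are slow — at 2 Hz sampling a GCaMP6s-like transient has little power
near the Nyquist frequency — and the median is immune to the sparse
spectral lines that regular intra-burst pulse trains place in the band.
The estimate is therefore essentially independent of event rate. The
time-domain estimator remains available as `method = "diff_quantile"`
(with `breakdown_quantile = 0.5` giving the classical first-difference
MAD). On long recordings the spectral estimate is computed per ~5-min
block and interpolated, so the threshold also tracks slow changes of the
noise scale; this is what makes the pulse count invariant (to within
0.5%) under additive exponential drifts of up to half the baseline,
which locally dilute dF/F amplitudes and noise by the same factor.

### Peak picking

The dF/F trace is boxcar-smoothed over `smooth_s` = 1.5 s (3 samples at
2 Hz). Smoothing buys the detectability of the small RP1 pulses: at the
SNR-5 study condition an RP1 pulse stands 5 noise SDs tall in the raw
trace, which leaves no margin against a 4-SD threshold, while after
3-sample smoothing it stands ~7 SDs above the smoothed noise. The window
is deliberately shorter than the intra-burst interval so the ripple that
separates consecutive burst pulses survives (a boxcar as long as the
interval would cancel it entirely).

Local maxima of the smoothed trace are kept when their topographic
prominence (height above the higher of the two key saddles) reaches
`threshold_k = 4` times the (blockwise) noise SD; peaks closer than
`min_separation` = 2 s are pruned smaller-first. Reported pulse times
are refined to the raw-trace maximum within the smoothing window, which
removes the smoothing-induced lag on the asymmetric (fast-rise,
slow-decay) transients; amplitudes are raw dF/F at the refined peak;
prominences and half-prominence widths come from the smoothed trace.

### Burst grouping and classification

`group_bursts()` forms maximal runs of pulses with consecutive gaps
≤ `max_ipi` = 10 s and at least `min_pulses` = 3 members. The membership
minimum of 3 (not 2) is a deliberate robustness choice: prominence
thresholds at ~4 SD admit a few tens of borderline noise peaks per 2-h
trace, and with a minimum of 2 a single such peak landing within
`max_ipi` of one isolated RP1 pulse fabricates a burst; chance *triples*
within 10-s gaps essentially never occur, while genuine CB bursts carry
~11 pulses and are unaffected.

`classify_pulses()` labels every in-burst pulse CB. Isolated pulses are
RP1 when their amplitude is below `amplitude_ratio` = 0.7 times the
median CB amplitude; larger isolated pulses count as single-pulse CB
events only when `min_pulses = 1` and are otherwise flagged
`unassigned`. For muscle recordings (`tissue` `"ectoderm"` or
`"endoderm"`) the RP1 set is forced empty — RP1 pulses are a neuronal
signature absent from muscle activity — and all detected pulses are CB
candidates.

`summarize_events()` reports, per recording: CB pulse number; burst
count; CB total time (sum of burst durations); CB pulse frequency
(pulses per minute of burst time, i.e. the intra-burst frequency, 0 when
there is no burst time); RP1 pulse number; RP1 total time (sum of RP1
half-prominence widths — pulses have no onset/offset of their own); and
RP1 frequency (pulses per hour of recording).

All five detection knobs (`baseline_window`, `threshold_k`,
`min_separation`, `max_ipi`, `min_pulses`, `amplitude_ratio`) are
surfaced in `analyze_trace()` and the CLI; their defaults are artifact
choices calibrated on the generator, not measured properties of real
recordings.

## Width morphometry

`segment_body()` thresholds each frame with Otsu's method refined by
isodata iteration — the threshold converges to the midpoint of the
background and foreground mean intensities, which places the cut at half
coverage on the blurred body outline; a raw Otsu cut on near-binary
frames can sit well above half coverage and systematically erodes the
rim — then keeps the largest connected component and fills holes
(EBImage primitives). A frame with no usable foreground is flagged
invalid; isolated invalid frames are linearly interpolated and more than
20% invalid frames is an error.

`fit_ellipse()` computes the moment-equivalent ellipse: axis lengths are
four times the square roots of the eigenvalues of the covariance of the
foreground pixel coordinates. A `1/12` term (the variance of a unit
pixel) is added to each coordinate variance so that pixelated masks of
continuous shapes are measured without point-sampling bias; collinearity
is judged on the raw moments first so degenerate masks still error. The
minor axis is the body-column width — the only ellipse scalar that
corresponds to "width of the body column" — and the major axis the
length. On rendered ellipses spanning axes 20–200 px and all
orientations, axis recovery error stays below 1.5% (most of which is the
irreducible pixelation of the smallest shapes). Widths are in pixels;
the CLI `width` subcommand converts to micrometres when `--pixel-size`
is given.

`detect_cycles()` finds local width minima with prominence at least 5%
of the trace range, separated by `min_period` = 60 s; their mean is the
average end-of-elongation width, reported as missing (not zero) when no
minimum exists. `count_contractions()` counts excursions in which body
length falls below `1 - shortening_fraction` (default 30% shortening) of
the preceding local maximum and recovers — an automated surrogate for
manual contraction scoring.

## Condition statistics

`t_test_unpaired()` is the pooled-variance (Student's, not Welch)
two-tailed t test, `df = n_a + n_b - 2`, matching the named test of the
original workflow; degenerate zero-variance inputs follow a documented
convention (p = 1 for equal means, p = 0 otherwise).
`anova_tukey()` runs fixed-effects one-way ANOVA and Tukey HSD with the
Tukey–Kramer unequal-n correction; studentized-range probabilities and
quantiles come from R's `ptukey()`/`qtukey()`, which the test suite
cross-checks against a studentized-range CDF evaluated by direct
numerical integration, and against `stats::TukeyHSD()`. For Tukey rows
`significant` (p < 0.05) coincides exactly with 0 lying outside the
simultaneous CI, since both derive from the same studentized-range
quantile. Pairs are reported in the order the groups are supplied, so
`control, low, high` reproduces the conventional "Ctr vs low, Ctr vs
high, Low vs high" row order. `build_report()` assembles the published
table shape — one row per comparison with method, 95% CI of the
difference, significance and p value — using Tukey for factors with
three or more levels and the t test for two-level factors, with no
additional multiple-testing correction across metrics. With two groups
`anova_tukey()` refuses and directs the caller to `t_test_unpaired()`;
the identity `F = t^2` is covered by the tests.

## Validation design and what it does (not) show

The test suite and `scripts/acceptance.R` validate, at the package's
design scales:

- detection fidelity on one hundred 2-h, 2-Hz recordings at the SNR-5
  defaults: pulse F1 and ±1 s timing, burst-count recovery within ±1,
  CB/RP1 class accuracy, CB pulse-number recovery within 5%;
- the ellipse oracle on rendered ellipses (axes 20–200 px, orientations
  0–π) and end-of-elongation width recovery within 2% through the full
  movie → segmentation → fit → cycle pipeline;
- the statistics against a 10^5-draw permutation oracle, the
  integration oracle, and a 10^4-simulation null calibration of the
  Tukey family-wise error rate (0.05 ± 0.01);
- the headline property: one hundred replicates of the three-condition
  experiment (multipliers 1.5/1.0/0.5, n = 8 recordings of 600 s)
  recover the ordering low > control > high of CB pulse numbers and a
  significant Tukey low-vs-high comparison in ≥95% / ≥90% of
  replicates — the synthetic analogue of the bidirectional osmolarity
  finding. Recordings of 600 s (rather than 2 h) keep one hundred
  replicates affordable; the power analysis above is for exactly this
  size.

What passing these tests shows is that the *pipeline* is correct and
well calibrated under the generator's assumptions: stationary Poisson
burst timing, regular pulse trains, a single global kernel, white
multiplicative noise, an elliptical body on a dark background, no
motion. Real recordings break several of these — behaviour is
non-stationary, amplitudes vary within bursts, the animal translates and
occludes itself, and tentacles violate the ellipse model — so numeric
performance on real data will be worse than the synthetic figures, and
the defaults (especially `threshold_k` and `amplitude_ratio`) should be
re-examined per dataset. The generator intentionally does not model
water-influx biophysics (the osmolarity multiplier stands in for the
mechanism), multi-animal wells, foot detachments, or the endodermal RP2
circuit. One further known artefact: because RP1 pulses are suppressed
around burst windows, recovered RP1 counts co-vary slightly with the CB
rate across conditions, whereas RP1 activity is osmolarity-independent
in the biology; comparisons of synthetic RP1 metrics across conditions
should keep that in mind.

## Reproducibility

Every stochastic step is seeded: `simulation_config(seed = )` makes
events, traces and geometry bit-reproducible, and `run_experiment()`
derives per-recording seeds from its master seed so that fixed-seed
reruns produce byte-identical summary and report CSVs (verified by
checksum in the tests). The run manifest records the tool version,
config snapshot, per-recording seeds and output checksums.
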