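# hydrapulse

Analysis of whole-body calcium imaging in the cnidarian *Hydra
vulgaris*. The package is written for experimenters who record
whole-body GCaMP fluorescence of *Hydra* neurons or epitheliomuscular
cells in mounted preparations and need to quantify, per recording, the
activity of the two dominant ectodermal patterns — **contraction bursts
(CB)**, clusters of large calcium pulses that accompany each
longitudinal body contraction, and **RP1** pulses, the smaller isolated
quasi-periodic events of the elongation circuit (absent in muscle
recordings) — and to compare those readouts, together with body-column
width, across experimental conditions such as media osmolarity.

## What it computes

Given a movie stack (multi-page TIFF) or a pre-extracted whole-body
fluorescence trace `F(t)`:

- **dF/F normalisation**: `(F - F0)/F0` with `F0` a running 10th
  percentile, removing photobleaching and slow drifts.
- **Pulse detection**: local maxima of the lightly smoothed trace whose
  topographic prominence exceeds `k = 4` times a spectral noise SD
  estimate (median high-band periodogram ordinate, robust to arbitrary
  event density).
- **Burst grouping**: maximal runs of pulses with inter-pulse intervals
  ≤ 10 s and at least 3 members; **classification**: in-burst pulses are
  CB, small isolated pulses (amplitude < 0.7 × median CB amplitude) are
  RP1, and muscle-tissue recordings force the RP1 set empty.
- **Activity summary** (per recording): CB pulse number, burst count,
  CB total time (Σ burst durations), CB pulse frequency (pulses/min of
  burst time), RP1 pulse number, RP1 total time, RP1 frequency.
- **Width morphometry**: per-frame Otsu+isodata segmentation, the
  moment-equivalent ellipse (axes = 4√eigenvalues of the pixel
  covariance), width = minor axis; contraction-cycle minima give the
  average end-of-elongation width.
- **Statistics**: mean ± SEM, two-tailed unpaired Student's *t*, and
  one-way ANOVA with Tukey's multiple comparison test (Tukey–Kramer
  CIs from the studentized-range distribution), assembled into a
  publication-style comparison table.
- **Synthetic recordings**: a fully ground-truthed generator of traces
  and width movies, with osmolarity-dependent CB rates
  (multipliers low 1.5 / control 1.0 / high 0.5), used to validate the
  entire pipeline; `run_experiment()` runs the three-condition
  experiment end to end.

See `vignettes/hydrapulse-methods.Rmd` for the models, parameter
defaults and their rationale, and known limitations.

## Worked example

Simulate a 30-min control recording, run detection, and score it against
the generator's ground truth:

```r
library(hydrapulse)

cfg <- simulation_config(duration = 1800, condition_label = "control",
                         seed = 42)
ev  <- simulate_events(cfg)
ev
#> <ground_truth> 29 bursts, 336 CB + 17 RP1 pulses over 1800 s

tr  <- render_trace(ev, cfg)
res <- analyze_trace(tr)
res$summary
#>  cb_pulse_number burst_count cb_total_time_s cb_pulse_frequency_per_min
#>              328          28           754.5                    26.0835
#>  rp1_pulse_number rp1_total_time_s rp1_frequency_per_h recording_duration_s
#>                19         55.49958                  38                 1800

score_detection(res$pulses, ev, tolerance = 1)[c("precision", "recall", "f1")]
#> precision 0.991, recall 0.980, F1 0.986
```

The detector recovered 28 of 29 bursts (the last burst is clipped by the
end of the recording) and 328 CB pulses of 336, at 99% precision. The
activity summary says the animal spent 754.5 s (42% of the recording)
in contraction bursts, firing ~26 CB pulses per minute of burst time,
with 19 detected RP1 pulses (38/h).

A full synthetic osmolarity experiment — 8 recordings of 600 s per
condition, detection, summaries, and Tukey comparisons per metric:

```r
ec  <- experiment_config(n_per_condition = 8, duration = 600, seed = 1)
out <- run_experiment(ec, out_dir = "run1", quiet = TRUE)
aggregate(cb_pulse_number ~ condition, out$summaries, mean)
#>   condition cb_pulse_number
#> 1   control          73.125
#> 2      high          47.750
#> 3       low         114.750

out$anova$cb_pulse_number
#> One-way ANOVA: F(2, 21) = 11.46, p = 0.0004326
#>      description      method estimate    ci_low    ci_high significant      p_value
#>   control vs low anova_tukey  -41.625 -77.24989  -6.000111        TRUE 0.0202587577
#>  control vs high anova_tukey   25.375 -10.24989  60.999889       FALSE 0.1954442225
#>      low vs high anova_tukey   67.000  31.37511 102.624889        TRUE 0.0003139765
```

Group mean CB pulse numbers are ordered low > control > high — the
synthetic analogue of the bidirectional osmolarity effect — and the
low-vs-high Tukey comparison is significant (95% simultaneous CI of the
difference 31.4 to 102.6 pulses, p = 0.0003). `run1/` contains the
per-recording summary CSV, the comparison report and a JSON manifest
(seeds, version, checksums); reruns with the same seed are
byte-identical.

A command-line wrapper with `simulate`, `extract`, `detect`, `width`,
`compare`, `run-experiment` and `version` subcommands is installed at
`system.file("cli/hydrapulse.R", package = "hydrapulse")`.

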