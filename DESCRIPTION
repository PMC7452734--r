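Package: hydrapulse
Title: Whole-Body Calcium Imaging Analysis of Hydra Contractile Activity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for whole-body calcium imaging of the
    cnidarian Hydra vulgaris. Extracts whole-body fluorescence traces from
    movie stacks, detects contraction-burst (CB) and rhythmic-potential
    (RP1) calcium pulses with inter-pulse-interval burst grouping and
    per-recording activity summaries, measures body-column width by
    moment-based ellipse fitting with per-cycle end-of-elongation width,
    and compares experimental conditions (e.g. media osmolarity) with
    Student's t tests and one-way ANOVA followed by Tukey's multiple
    comparison test. Includes a ground-truthed synthetic-recording
    generator with osmolarity-dependent burst rates for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
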