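Package: fixsacc
Title: Fixational Saccade and Square-Wave Jerk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterization of fixational saccades (from
    microsaccades to saccadic intrusions) in 2D eye-position recordings.
    Implements adaptive velocity-threshold saccade detection with
    acceleration-based bound refinement, dynamic-overshoot merging and a
    binocular overlap filter; classifies square-wave jerks (SWJs) with a
    continuous similarity index; computes per-subject saccadic metrics
    (rate, magnitude, main-sequence slope, normalized vertical component)
    and SWJ coupling analyses; and compares subject groups with one-way
    ANOVA, Tukey HSD and leave-one-out linear discriminant analysis. A
    synthetic fixation-trace generator with control, Parkinson's disease
    and progressive supranuclear palsy presets provides ground-truth
    annotations for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
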