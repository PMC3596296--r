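# fixsacc

Analysis of fixational saccades — from microsaccades to square-wave jerks
(SWJs) — in 2D eye-position recordings, for oculomotor researchers and
clinical neurophysiologists studying fixation instability in parkinsonian
disorders and ataxias.

During attempted fixation, saccades of all sizes interrupt gaze. SWJs, the
most common saccadic intrusion, pair a saccade away from the target with a
corrective return saccade a short interval later. Their frequency, size and
dynamics differ systematically between healthy subjects, Parkinson's
disease (PD) and progressive supranuclear palsy (PSP), and the properties
of fixational saccades can help assign subjects to diagnosis groups.

The package implements:

- **Adaptive saccade detection** in 2D velocity space. Velocity comes from a
  5-point smoothed differentiator; the threshold per component is
  `eta = lambda * sqrt(median(v^2) - median(v)^2)` (robust to the saccades
  themselves), with acceleration-based bound refinement, merging of dynamic
  overshoots (gaps < 20 ms), and a binocular overlap filter (>= 1 shared
  sample in both eyes).
- **SWJ classification** by a continuous index in [0, 1]: the geometric mean
  of direction dissimilarity `(1 - cos(d_theta))/2`, magnitude similarity
  `1 - |m1 - m2|/(m1 + m2)` and temporal proximity
  `max(0, 1 - |dt - 0.2|/0.2)`; an ideal SWJ (equal, opposite, 200 ms apart)
  scores exactly 1, and pairs above 0.6 are SWJs.
- **Per-subject metrics**: saccade rate, magnitude, main-sequence slope
  (peak velocity vs magnitude), normalized vertical component, SWJ coupling
  (logistic regression of membership on magnitude), intra-SWJ intervals,
  and position-error / return-latency analyses.
- **Group statistics**: one-way ANOVA, Tukey HSD, and leave-one-out linear
  discriminant analysis with fold-wise standardization and a ridge-stabilized
  pooled covariance.
- **A synthetic trace generator** (drift + main-sequence minimum-jerk
  saccades + error-triggered SWJ returns + measurement noise) with control,
  PD and PSP presets, producing ground-truth annotations for every event.

## Worked example

```r
library(fixsacc)

out  <- simulate_trace(sim_preset("psp", duration = 120, seed = 7))
summ <- summarize_subject(out$trace)
summ
#> <subject_summary> sim-seed7 (psp)
#>   saccades: 284 (2.37 /s), SWJs: 111
#>   magnitude: mean 1.30 deg (median 1.19)
#>   main-sequence slope: 42.3 (deg/s)/deg
#>   vertical component: 0.16
#>   mean intra-SWJ interval: 152 ms
```

A 120 s PSP-preset recording is simulated and pushed through the full
pipeline. The summary recovers the preset's generating parameters —
saccade rate 2.1/s, mean magnitude 1.38 deg, main-sequence slope 43
(deg/s)/deg (slow saccades), vertical component 0.16 (strongly horizontal)
— to within sampling error; 111 of the 284 detected saccade pairs are
classified as SWJs, with intra-SWJ intervals near the generator's latency
model.

Recordings can also be read from CSV (`read_trace()`, two-line header with
`rate=` metadata, columns `t,x,y[,x2,y2]`), masked around blinks
(`mask_gaps()`), and written back (`write_trace()`). A thin command-line
wrapper lives in `inst/cli/fixsacc.R`
(`simulate` / `detect` / `swj` / `metrics`).

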