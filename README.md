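# patchpace

Analysis of striatal patch (striosome) neuron calcium activity during
light/dark-box behavior: how ΔF/F relates to zone occupancy, locomotor
speed, acceleration versus deceleration, and zone-crossing moments.

The package is for researchers analyzing simultaneous behavioral tracking
(per-frame positions at ~30 Hz in a two-zone arena) and calcium signals
(per-neuron miniscope ΔF/F or a fiber-photometry trace with a control
channel). It implements the full pipeline as ordinary R functions, plus a
seeded synthetic-session generator with ground-truth labels so that every
stage is verifiable without any recording.

## The statistics at its core

* **BIL effect.** Frames around a zone crossing are split into body-in-light
  (BIL: pre-crossing frames of into-dark events, post-crossing frames of
  into-light events) and body-in-dark (BID) masks within the approach
  (−2 to −0.6 s) and retreat (+0.6 to +2 s) windows. The BIL effect of a
  signal *y* is `mean(y | BIL) − mean(y | BID)` per phase, with a
  percentile-bootstrap CI resampling transitions as the unit.
* **ADI (acceleration/deceleration preference index).** With acceleration
  binarized at ±0.4 cm/s², `ADI = (auROC − 0.5) × 2`, where auROC
  discriminates acceleration-frame from deceleration-frame activity by the
  Mann–Whitney rank statistic (ties counted half). `ADI = −1` means activity
  confined to deceleration; `|ADI| > 0.8` flags a deceleration-predicting
  (DP) neuron.
* **Speed classes.** Spearman rank correlation between ΔF/F and speed at a
  per-animal Bonferroni level `0.05/n` gives `L+`/`L−`; otherwise a
  quadratic fit `ax² + bx + c` with R² > 0.3 gives `Q+`/`Q−`.
* **Zone preference.** Two-sided Mann–Whitney on frame-wise ΔF/F between
  zones at `0.05/n`, with block decimation (1 frame/s) against serial
  dependence.
* **Event-windowed cross-correlation.** Within 4-s acceleration events
  (window mean speed above 5 cm/s imaging / 6 cm/s photometry), the lagged
  correlation (±1 s) of ΔF/F with speed or acceleration; the largest-|r|
  lag is reported and events significant at p < 0.05 are averaged per
  animal and context.

## Worked example

`analysis/01_simulate_session.R` … `05_coupling.R` run this end to end and
write tables under `results/`. In brief:

```r
library(patchpace)

arena <- arena_config()                        # 40 x 29 cm box, 30 Hz
track <- simulate_trajectory(
  arena, behavior_gen_config(duration = 600, ou_tau = 2,
                             speed_smooth_s = 0.8, noise_sd = 2.5,
                             seed = 101))

pop <- neuron_population(15, classes = c("L+", "L-", "Q+", "Q-",
                                         "light", "dark", "DP", "null"))
sim <- simulate_traces(track, neuron_gen_config(pop, kernel_tau = 0.25,
                                                seed = 102))

res <- run_pipeline(track, sim$traces, pipeline_config(), "sim1")
```

The session has 19 zone transitions; the behavioral summary prints

```
rest fraction: dark 0.28, light 0.04; max sustained speed 13.9 cm/s
BIL effect on speed: 2.12 cm/s (95% CI 1.05 to 3.30)
```

— the animal rests mostly in the dark zone, and speed around crossings is
~2 cm/s higher while the body is in the light (the generator programmed a
2 cm/s increment). Classification of the 120 neurons gives

```
speed-related 75%, zone-related 50%, DP 12%, categorized 88%
DP x zone/speed-free: fisher p = 3.28e-11
zone recovery 100%, DP recovery 100% in this session
```

Zone-preferring and speed-class labels overlap heavily here because in a
naturalistic session the animal genuinely runs faster in the light, so
zone-driven neurons are also speed-correlated — the methods vignette
explains this confound and the symmetric validation protocol
(`recovery_protocol()`) that removes it. The coupling stage reports, per
context, the mean r and lag of significant events; for this
deceleration-coupled population the acceleration correlations are strongly
negative within zones (mean r ≈ −0.6 to −0.7).

## Layout

```
R/                  implementation (behavior, traces, tuning, coupling,
                    pipeline, synthetic data, I/O)
analysis/01..05     numbered drivers: simulate -> segment -> condition ->
                    classify -> couple; write results/
scripts/acceptance.R   validation quantities as JSON
tests/testthat/     unit suites per module + validation studies
vignettes/methods.Rmd  the model, parameters, design choices, limitations
```
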