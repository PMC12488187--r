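---
title: "Methods: zone, speed, and deceleration tuning in the light/dark box"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone, speed, and deceleration tuning in the light/dark box}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchpace)
```

## The analysis problem

A mouse explores a two-zone box: a brightly lit, anxiogenic *light* zone and
a sheltered *dark* zone (40 x 29 cm, tracked at 30 Hz). Simultaneously, the
activity of striatal patch (striosome) neurons is recorded as calcium
fluorescence (ΔF/F), either one trace per neuron (miniscope) or a single
population trace with a control channel (fiber photometry). The package
quantifies how that activity relates to where the animal is (zone), how fast
it moves (speed), whether it is accelerating or decelerating, and what
happens at the choice point of a zone crossing.

The pipeline has five stages, each exposed as ordinary functions:

1. **behavior** — speed and acceleration from tracked positions, zone
   transitions with body-in-light / body-in-dark (BIL/BID) windows, rest
   fractions, sustained speed, acceleration events, and the BIL-effect
   estimator.
2. **traces** — ΔF/F conditioning (3x-noise-floor zeroing, max-
   normalization), photometry double-exponential detrending, fluorescence
   event detection, timebase alignment.
3. **tuning** — per-neuron classification: zone preference, speed class,
   acceleration/deceleration preference (ADI), the deceleration-prediction
   (DP) flag, transition activity and BIL/BID selectivity.
4. **coupling** — event-windowed lagged cross-correlation between ΔF/F and
   speed or acceleration, per-animal summaries, transition-triggered
   averages.
5. **synthetic data** — a seeded generator producing trajectories and
   calcium traces with known ground truth, so each stage above is testable
   without any recording.

## Behavioral definitions and their parameters

| parameter | default | units | meaning |
|---|---|---|---|
| acceleration threshold | 0.4 | cm/s² | binarize into accelerating / decelerating / neither |
| rest cap | 2 | cm/s | "restful" speed |
| sustained-speed run | 20 | frames | max speed held for ≥ this run |
| transition window | ±0.6 to ±2 | s | approach / retreat analysis windows |
| acceleration-event window | 4 | s | centered on an acceleration onset |
| event mean-speed filter | 5 / 6 | cm/s | imaging / photometry modality default |
| zone debounce | 0.5 | s | residencies shorter than this are jitter |

A *transition* is scored at the first frame of a new zone residency. Frames
in the approach window (−2 to −0.6 s) and retreat window (+0.6 to +2 s) are
split into **BIL** (body in light: pre-crossing frames of into-dark events,
post-crossing frames of into-light events) and the complementary **BID**
masks; the two masks partition each window exactly. The **BIL effect** of a
signal is the mean over BIL frames minus the mean over BID frames within a
phase, computed per transition and averaged; its confidence interval is a
percentile bootstrap that resamples transitions (stratified by direction) as
the exchangeable unit. We average per-transition window means rather than
pooling frames so that every transition carries equal weight and the
bootstrap unit matches the estimator.

Two conventions that the standard assay description leaves open are fixed
as follows. An
acceleration *onset* is the rising edge of an accelerating run. An
acceleration event's *context* is decided by its center frame: within ±2 s
of a crossing it is a transition event of that crossing's direction,
otherwise it is a within-zone event. Zone changes separated by less than
0.5 s are merged before scoring (tracking jitter at the divider; the
tail-base-follows-nose crossing rule used with multi-point pose tracking
needs a body model that a single tracked point cannot provide). Speed is differentiated after a
5-frame boxcar for acceleration analysis; histograms and rest fractions use
the raw finite-difference speed.

The mean-speed filter for acceleration events has different conventional
values by modality (5 cm/s for single-cell imaging, 6 cm/s for photometry);
both are recorded as per-modality defaults and both are overridable.

## Trace conditioning and events

Miniscope ΔF/F is zeroed wherever it falls below 3x the per-neuron baseline
noise level, then max-normalized to [0, 1]. The noise floor is estimated as
`1.4826 * median(|Δx - median(Δx)|) / sqrt(2)` on the first-differenced
trace — differencing suppresses slow transients, making the estimate robust
to genuine calcium events; the multiplier rescales the MAD to a Gaussian SD.
Any externally supplied noise level can be passed instead. After
conditioning, the stored noise floor is rescaled by the same per-neuron
maximum, which makes conditioning idempotent.

Fluorescence events are local maxima of the conditioned (or flattened,
normalized photometry) trace above its mean + 1.5 SD, thinned so that no two
events are closer than 1 s; the higher peak wins and ties go to the earlier
peak. Inter-event intervals are assigned to the zone occupied at the earlier
event of a pair only when both events share the zone; cross-zone pairs are
dropped and counted rather than split, since a single interval spanning a
crossing belongs to neither zone cleanly.

Photometry channels are flattened by subtracting a least-squares double
exponential `a*exp(-t/tau1) + b*exp(-t/tau2) + c`. One reweighting pass
refits after excluding frames whose residual exceeds 3 robust SDs so that
transients do not drag the baseline; if the double-exponential fit fails to
converge the routine falls back to a single exponential plus constant and
records a warning. ΔF/F after flattening is the residual divided by the
fitted baseline curve.

## Tuning classification

**Zone preference** compares frame-wise ΔF/F between zones with a two-sided
Mann-Whitney test at level `0.05 / n`, where `n` is the number of identified
neurons in that animal (a per-animal Bonferroni correction). **Speed class**
computes the Spearman rank correlation between ΔF/F and speed first: a
significant correlation (same corrected level) gives `L+` or `L-` by sign.
Only when that fails is the activity-speed relation fitted with a quadratic
`ax² + bx + c`; a goodness of fit above 0.3 gives `Q+` (a > 0) or `Q-`
(a < 0). "Goodness of fit" is interpreted as the R² of the least-squares fit on
frame-wise data — one of several defensible readings of that phrase,
documented as this package's choice. The rank branch always takes
precedence.

Frame-wise samples are the comparison unit for both tests, because the
definitions reference activity *within* periods. Consecutive 30 Hz frames
are strongly autocorrelated, which inflates the effective test level, so
every classifier accepts a block-decimation factor (`decimate`, keep every
k-th frame); the pipeline default keeps one frame per second (k = 30). The
type-I study below shows this holds the family-wise false-positive rate near
nominal; without decimation the rates would be badly anticonservative.

The **acceleration/deceleration preference index** is
`adi = (auROC - 0.5) * 2`, where auROC discriminates acceleration-frame
activity (positive class) from deceleration-frame activity via the
Mann-Whitney rank statistic with ties counted half. `adi = -1` means
activity uniformly higher while decelerating. Frames labeled `neither`
(|acceleration| ≤ 0.4 cm/s²) are excluded — excluding them keeps the index a pure
two-class statistic rather than forcing near-zero accelerations into either
class. A neuron is **DP** (deceleration-predicting) when |adi| strictly
exceeds 0.8.

A neuron is **transition-active** when its conditioned ΔF/F exceeds
0.0238 (normalized units) at any frame within ±2 s of any crossing. That
constant is the conventional group-activity-derived default for this assay;
since its derivation depends on the recorded population, it is kept as an
ordinary, overridable parameter here.
Selectivity looks only at super-threshold frames inside the masked windows:
exclusively BIL frames → `BIL_selective`, exclusively BID → `BID_selective`,
both → `nonselective`. Frames in the ±0.6 s gap count toward activity but
not selectivity.

Category associations use Pearson's chi-square without continuity
correction, substituting Fisher's exact test when a 2x2 table has any
expected cell below 5.

## Cross-correlation within acceleration events

Within each 4-s acceleration event, both windows are centered and scaled and
the Pearson correlation of the overlapping segments is evaluated at every
integer-frame lag within ±1 s (a 1 s bound covers the sub-second
neural-behavioral lags typical of this preparation and is configurable). The reported value is
the correlation of largest magnitude — magnitude, not maximum, so that
negative acceleration coupling is captured — with ties broken toward the
smallest |lag| and then the negative lag. A positive lag means the signal
lags the behavior. Significance is the Pearson test at the best lag with
`window frames − 2` degrees of freedom; selecting the best lag inflates this
nominal level, so a circular-shift permutation p-value (1000 shifts) is
available as the rigorous alternative (`p_method = "permutation"`). Animal
summaries average r and lag over significant (p < 0.05) events per
context x target, and the group-level helper bootstraps animals.

## The synthetic-data generator

The generator is the package's ground-truth oracle, built so that every
downstream estimate has a programmed true value.

**Trajectory.** A zone-residency schedule (exponential dwells, floored at
5 s, dark residencies longer by `dark_dwell_bias`, default 2) drives a
discretized Ornstein-Uhlenbeck speed process that relaxes toward
zone-dependent set-points (defaults 8 cm/s light, 4 cm/s dark, matching the
faster locomotion observed under anxiogenic light). Scheduled rest bouts
(zone-dependent rates, default 6/min dark vs 1.5/min light) pull the
set-point to 0.8 cm/s with reduced noise; the process takes a moment to
relax into each bout, so bout frames are mostly, not entirely, below the
2 cm/s rest cap. The speed series is low-passed (0.5 s boxcar) to give it
the smoothness of real center-of-mass tracks — without this, accelerating/
decelerating bouts flip every few frames, which no calcium kernel could
resolve. Each crossing adds a symmetric Gaussian speed excursion (peak
4 cm/s, SD 0.5 s), and the programmed `bil_increment` is added on BIL-masked
window frames only. From 5 s before each crossing until 5 s after, the
set-point switches to the mean of the two zone set-points; the long lead-in
(≥4 relaxation time constants before the analysis window opens) guarantees
that `bil_increment` is the *only* systematic BIL/BID asymmetry, making it
the exact recovery target of the BIL-effect estimator.

Positions advance along a smooth elliptical loop inset in the current zone —
a deliberate abstraction of the real U-shaped floor plan. On a smooth loop
the per-frame chord equals the arc to O((v·dt)²/R²), so speed recomputed
from positions reproduces the generated series to ~10⁻⁴ cm/s; at a scheduled
crossing the position jumps to the other zone's gate (a handful of frames
per session). The analysis consumes speed, zone labels, and crossing times,
none of which are affected; recomputing speed from written positions is
exact everywhere except those crossing frames. A single tracked point
stands in for the nose/center/tail-base distinctions, so the tail-base
transition rule is approximated by the divider crossing.

**Traces.** Each neuron's event rate is
`max(0, baseline + zone_gain·[light] + f(speed) + decel_coupling·[decelerating]
+ bil_gain·[BIL] + bid_gain·[BID])` with `f` linear or quadratic. Events are
Poisson per frame, convolved with an exponential kernel (`kernel_tau`), plus
Gaussian noise. Ground-truth labels follow deterministically from the signs
of the parameters; a neuron with no drive at all is emitted as a flagged
silent `none`/`none` record. The `bil_gain`/`bid_gain` fields extend the
generative model so transition-selectivity classification can also be
validated against ground truth.

**Determinism.** Seeds are explicit, required arguments; every stochastic
routine saves and restores the caller's RNG state, and identical seed +
config gives bit-identical output.

## The classifier-validation protocol

Recovery experiments use fixed, documented conditions
(`recovery_protocol()`): a 600-s session with *equal* speed set-points in
the two zones (10 cm/s), no rest bouts, no transition excursion or BIL
increment, slow smooth speed fluctuations (OU relaxation 3 s, SD 4 cm/s,
1 s low-pass, giving ~0.7 s accelerating/decelerating bouts), and fast
indicator kinetics (kernel 0.25 s, additive noise 0.02). Couplings are
strong relative to baseline (e.g., DP: 20 events/s during deceleration over
a 0.02/s baseline). Two choices deserve explanation:

* *Zone-symmetric speed.* In a session where light-zone speed exceeds
  dark-zone speed, a genuinely zone-tuned neuron is also genuinely
  speed-correlated and vice versa — the generator's one-cause-per-neuron
  labels would be wrong, not the classifier. Equalizing the set-points
  removes the confound so each classifier is scored on its own dimension.
* *Quadratic vertices at the realized median speed.* A parabola whose vertex
  is off the center of the sampled speed distribution carries a genuine
  monotone component, and the rank branch correctly claims it. The protocol
  therefore centers `Q±` neurons on the session's median speed, the regime
  in which the quadratic ground-truth label is semantically valid.

Under these conditions all seven non-null classes are recovered at ≥90%
(typically 100%), and 200 null sessions of 50 baseline-only neurons hold the
family-wise false-positive rate of zone and speed classification within
Monte-Carlo error of the nominal 5% when block decimation is on.

What passing these tests does *not* show: the generator's rate model is far
simpler than real striatal dynamics (no adaptation, no correlated noise
across neurons, no motion artifacts, no cross-session drift), its behavior
model has no pose, thigmotaxis, or goal-directed structure, and real
indicator kinetics are slower (GCaMP6s ~1 s decay) than the validation
kernel. Recovery rates here are upper bounds on what identical settings
would achieve on real recordings; conversely the *definitions* (windows,
masks, indices, tests) are exercised exactly as they would run on real data.

## Numerical choices and degenerate inputs

* Wilcoxon/Mann-Whitney and Spearman tests use asymptotic p-values
  (frame-wise data are heavily tied after conditioning; exact p-values are
  neither available nor needed at these sample sizes).
* A zone with fewer than 10 (decimated) frames, a constant speed window, or
  an empty acceleration/deceleration class yields an explicit flagged `NA`,
  never a silent number.
* `adi = 0.8` exactly is *not* DP (strict inequality); `detect_events`
  plateau peaks keep their first frame; cross-correlation lag ties prefer
  0, then the negative lag.
* The bootstrap stratifies by transition direction so each resample retains
  both directions; sessions missing a direction raise an error rather than
  returning a one-sided "effect".
* Problem sizes in the validation studies (600-s recovery sessions, 200
  null sessions of 300 s, 100 hour-long BIL sessions) were chosen as the
  smallest giving stable Monte-Carlo estimates of the quantities under
  test.

## Known limitations

* The 0.0238 transition-activity threshold is inherited as a constant; on
  data conditioned differently from the source extraction stack its
  percentile meaning will differ.
* The Pearson p-value at the best lag is anticonservative (use the
  permutation option when the significance filter matters).
* Mixed-effects modeling of BIL effects across animals is out of scope; the
  estimator here is the within-session window contrast with a bootstrap CI,
  and `group_bootstrap_ci()` aggregates animals nonparametrically.
* Reading a generator session back from tracking CSV and recomputing speed
  from positions reproduces the stored series except at the crossing
  frames (position-jump abstraction); use the stored speed or treat
  crossing frames as missing when differentiating externally supplied
  positions of discontinuous quality.
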