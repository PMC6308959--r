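---
title: "Methods: signal filtering and fuzzy heat-stroke risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal filtering and fuzzy heat-stroke risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whdd)
```

# Overview

`whdd` implements the on-body computation of a wearable heat-stroke
detection device as testable software. The chain is:

1. a one-minute resting **baseline** per user (heart rate and skin
   conductance, each validated against the adult resting range);
2. per-epoch **filter cascades** for heart rate (threshold → error →
   moving average) and body temperature (skin-to-core conversion →
   compensation/hold → moving average) on a 2 Hz stream;
3. per 60-epoch window, a **Mamdani fuzzy controller** mapping the
   filtered heart rate, filtered body temperature, conductance change
   from baseline, and an environmental danger coefficient onto a crisp
   heat-stroke risk indicator in [0, 40].

A session **simulator** generates latent physiological truth and
artifact-corrupted observations so every stage can be verified end to
end without hardware.

# Filter cascades

## Heart rate

The wrist photoplethysmographic sensor is disturbed by arm motion, so
three stages run per 0.5 s epoch.

**Threshold stage.** A reading outside `[hr_lower, hr_upper]`
(defaults 50 and 190 bpm) is replaced by the previous stored value.
The upper bound is the rounded age-predicted maximum heart rate
`hr_max(age) = 208 - 0.7 * age` (the Tanaka equation); 190 corresponds
to age 26. Failed readings are encoded as 0 by the sensor and fall out
of band automatically.

**Error stage.** For the epoch-to-epoch difference
`error = value - previous`:

* `error < -10` bpm: store `value - round(error * 1.05)` while the
  consecutive-low budget (6) lasts, else hold the previous value and
  reset the counter;
* `error > 25` bpm: store `value - round(error * 0.6)` while the
  consecutive-high budget (2) lasts, else hold and reset;
* otherwise the value passes unchanged.

Two readings of the pseudocode-style counter policy exist: counters
may persist across dead-band epochs (default) or reset on any normal
epoch (`reset_counters_on_normal = TRUE`). The default keeps the
stricter interpretation: a budget is only cleared when it is spent.
Note the low branch's gain of 1.05 adds back slightly more than the
full deviation, so an isolated drop is corrected past its origin by
5 % of the error; the gain pair (1.05, 0.6) is a device calibration
constant and is exposed in `filter_config()` rather than second-guessed.

**Moving average.** After 60 stored epochs the window mean is emitted
(`hr_window_mean()`), the window resets, and the emitted mean seeds the
*predecessor register* used by the threshold and error stages for the
first epoch of the next window. The resting heart rate seeds the
register before the first window. Keeping the seed in a register
rather than in a window slot means every window averages exactly 60
sensor epochs, so a stream of `n` epochs yields `floor(n / 60)`
packets with only the final partial window left over, while the error
stage stays continuous across window boundaries.

## Body temperature

Skin temperature from the infrared sensor is converted to core
temperature through the gradient model
`t_core = t_skin + alpha * (t_skin - t_ambient)`; `alpha` depends on
the measurement site (rectal 0.0699, head 0.3094, torso 0.5067, hand
0.7665, foot 2.1807, via `body_part_alpha()`). The default is the hand
coefficient because the sensor sits on the inner wrist.

The compensation map `temp_compensate()` then corrects the systematic
underestimate of a sweating skin surface:

* `t_core` in [31, 35] °C: `t_core + (35 - t_core) * 1.5` — an affine
  map with slope −0.5 that stretches [31, 35] onto [38, 35];
* `t_core` in (35, 40) °C: identity;
* anything else: the average human body temperature, 36.0 °C.

Both branches give 35 at 35 °C, so the map is continuous there and
sends every real input into [35, 40). Band edges are closed on
[31, 35] and open on (35, 40); exactly 40.0 °C is treated as abnormal
and falls to 36.0. An alternative lower edge of 28 °C for the
compensation band (the firmware variant) is available through
`filter_config(comp_band = c(28, 35))`; the default keeps the
narrower band stated with the compensation equation, so readings in
[28, 31) are treated as abnormal.

On top of the pure compensation map, the streaming stage
(`temp_threshold_step()`) applies a *hold rule*: within the
compensation band a newly compensated value is stored only when the
deviation `35 - t_core` differs from the previously stored deviation;
an unchanged deviation repeats the previous slot. The rule is kept as
a separate, optional stage (`use_hold_rule`) so the compensation map
remains testable on its own. The temperature predecessor register is
initialised to the 36.0 °C fallback, since no temperature baseline is
acquired before a run.

# Baseline acquisition

`acquire_baseline()` consumes 120 consecutive samples (one minute at
2 Hz) and averages them. The average is rejected — and the next 120
samples tried, up to `max_attempts` (default 3; the device loops
indefinitely, which is not testable) — when it is zero (sensor not
detecting), non-finite, or outside the adult resting range: 50–90 bpm
for heart rate, 10–50 µS for skin conductance. Individual zero samples
within an otherwise valid minute are kept; only the average is
checked. The device literature labels the 10–50 µS range "skin
resistance" although µS is a conductance unit; this package treats the
channel as conductance in µS throughout.

# Environmental danger coefficient

The danger coefficient summarises environmental heat stress as
`danger_coefficient(t, rh) = t + rh / 10`. This linear form reproduces
both study environments exactly — an evening outdoor track at 23.5 °C
and 80 % RH scores 31.5, an indoor gym at 28.9 °C and 68.2 % RH scores
35.72 — and the humidity weight is configurable. It plays the role of
the "safety factor" input of the fuzzy controller; the package treats
the two as the same quantity.

# Fuzzy risk controller

The controller is Mamdani-style: trapezoidal memberships, min-AND rule
firing, max aggregation of clipped output terms, and centroid
defuzzification on the output universe [0, 40] discretised at 0.05.
Everything — membership breakpoints, the rule table, the
defuzzification method — is data (`default_fuzzy_config()`,
YAML-serialisable), not code, and is replaceable per user.

**Input partitions.** Each input has three severity terms over a
physical universe: heart rate [50, 200] bpm (anchored at the user's
resting rate and age-predicted maximum, so the controller adapts to
the individual); body temperature [35, 40] °C; conductance change
[−30, +10] µS (sweat shutdown drives the conductance down, so severity
grows in the negative direction); danger coefficient [20, 45].

Adjacent terms are deliberately laid out as *staircase trapezoids*:
the higher term's plateau begins at or before the point where the
lower term's down-ramp starts, so at most one term is ramping at any
point and the strongest membership is always 1. With a complementary
triangular partition the two memberships cross at 0.5, the clip of any
output term fed by both sides dips at the crossover, and the
defuzzified risk dents non-monotonically. The staircase layout plus a
monotone rule table makes the crisp risk non-decreasing in every
stress-increasing direction, which is the behaviour a risk indicator
must have.

**Rule table.** The 81 rules (3 terms × 4 inputs) are generated from a
weighted severity score: with term grades 0–2 per input and weights
heart rate 0.45, body temperature 0.20, danger coefficient 0.30,
conductance change 0.05, the normalised score in [0, 1] is scaled to
the four output terms (round half away from zero). The weight ordering
encodes the empirically observed reaction chain — heart rate responds
first and strongest, body temperature later, skin response last — and
makes a near-maximal heart rate in a severe environment sufficient to
reach the dangerous zone. Because the table is plain data, a user can
replace it wholesale.

**Output zones.** Output terms sit in the four risk zones: Safe
trap(0, 0, 5, 12), Attention tri(8, 15, 22), Warning tri(18, 25, 32),
Dangerous trap(28, 35, 40, 40). For the continuous indicator the zone
boundaries are half-open — Safe [0, 10], Attention (10, 20], Warning
(20, 30], Dangerous (30, 40] — so the level mapping is total. The
Warning and Dangerous zones correspond to the device's "alert" and
"interdiction" modes. When no rule fires at all the aggregate is empty
and the risk is defined as 0 (Safe).

**Sensitivity.** On the central operating region (heart rate 90–185
bpm, body temperature 36–39.5 °C, indoor environment), the mean
absolute risk slope per unit of universe-normalised input is about
2.5× larger along the heart-rate axis than along the temperature axis
— the controller's risk surface rises primarily with heart rate, which
matches the physiological reaction ordering above and is asserted as a
property test.

# Session simulator

`simulate_session()` generates what the sensors *should* read (latent
truth) and what they *do* read (observations) for a staged running
protocol. The default indoor protocol is 8 km/h × 10 min, 10 km/h ×
2 min, 12 km/h × 3 min at 28.9 °C / 68.2 % RH; the outdoor preset is a
stylised evening 2-km track run at 23.5 °C / 80 % RH.

**Latent dynamics.** No ground-truth physiological traces exist for
the original experiments, so the simulator uses the simplest dynamics
consistent with the observed reaction ordering: first-order
relaxations with time constants 45 s (heart rate), 240 s (core
temperature), 420 s (conductance). Per stage, heart rate relaxes
toward `relax_hr + effort * (fitness * hr_max(age) - relax_hr)` with
`effort = speed / 12 km/h` capped at 1; core temperature toward
`36.6 + 2.7 * effort` °C (asymptote 39.3 °C at full workload — bounded
below the 40 °C danger line, since none of the study runners reached
it); conductance toward a sweat-saturation floor 60 % below baseline.
The `fitness` parameter is heart-rate *responsiveness*: the fraction
of the age-predicted maximum toward which the runner is driven at full
workload. Deconditioned runners operate nearer their maximum, so the
"irregular exerciser" presets carry values near 1 (0.96–0.97) and the
trained presets 0.75–0.78.

**Observation model.** `artifact_model()` corrupts the latent truth
with per-sample dropouts (probability 0.01, reading 0), heart-rate
spikes (probability 0.02, drawn from [0, 49] ∪ [191, 220] bpm so the
threshold filter is genuinely exercised), Gaussian noise (2 bpm,
0.15 °C, 0.5 µS), and a sweat-induced skin-temperature depression that
saturates at `temp_sweat_bias` (default 1.0 °C) as cumulative workload
accumulates. The observed skin temperature is the *inverse* of the
skin-to-core map applied to the latent core temperature, minus the
sweat bias — i.e. what the infrared sensor would actually report. A
session seed fans out to per-channel sub-seeds so channels can be
regenerated independently; the same seed reproduces bit-identical
streams.

**Feedback events.** A discomfort button press is logged the first
time latent heart rate exceeds `discomfort_hr_frac * hr_max(age)`, at
most once per session.

**What the simulator does not emulate.** Physiologically validated
thermoregulation; cardiovascular drift and inter-beat variability;
humidity/temperature drift during a session; device-specific GSR
normalisation; the real subjects' individual traces. Passing tests
therefore demonstrate that the pipeline behaves correctly under the
*stated* artifact and dynamics model, not that it is clinically
validated on real runners.

# Numerical and design choices

* **Rounding** in the error filter is half away from zero on the bpm
  scale (`round_half_away()`), the everyday reading of "Round(·)" for
  integer heart rates; base R's banker's rounding would differ at .5.
* **Pipeline order** is threshold stage first, then error stage, both
  operating on stored (already-filtered) values — the error stage
  compares against the previous *stored* slot, not the previous raw
  reading.
* **Window bookkeeping**: windows are sample-indexed (60 epochs),
  never wall-clock-indexed; the device's nominal cadences (2 Hz
  sampling vs 15 ms collection cycles) cannot both hold in software,
  so one window is defined as 60 epochs ≈ 30 s at 2 Hz.
* **Centroid resolution** 0.05 on [0, 40] (801 points) makes the
  discretisation error of the defuzzified risk ≪ 0.05 risk units.
* **Display rounding** in comparison reports: heart rates to
  integers, temperatures and errors to two decimals. The underlying
  statistics are kept at machine precision; e.g. the bundled
  ten-pair temperature table has mean signed error 0.144 °C, displayed
  as 0.14.
* **Risk output type**: the risk indicator is real-valued; the
  device's integer zone labels ("21–30", "31–40") are represented by
  the half-open zone boundaries above.
* **Per-user adaptation** is exposed by rebuilding
  `default_fuzzy_config(relax_hr, age)` from the acquired baseline
  (done automatically by `run_pipeline()`); no parameter learning is
  performed.

# Problem sizes

The test suite and examples run entire simulated sessions at their
natural size: 1800 epochs (15 min at 2 Hz) per runner, 30 windows per
session, cohorts of four (indoor) and five (outdoor) runners, fuzzy
surfaces on grids of roughly 30 × 15 to 60 × 25 points. These sizes
keep the full suite in the tens of seconds on a single CPU while
exercising every window boundary and both alert transitions.

# Known limitations

* The filter gain pair (1.05, 0.6) and the compensation slope 1.5 are
  device calibration constants; they are configurable but no
  re-calibration procedure is provided.
* The danger coefficient is a linear reconstruction from two printed
  value pairs; other heat indices (WBGT, humidex) are not implemented.
* The fuzzy rule base is a documented default, not the original
  device's (unpublished) rule base; conclusions about absolute risk
  values transfer only after per-deployment calibration.
* Alert-timing comparisons depend on the simulator's discomfort
  model; with synthetic runners the system-vs-feedback lead is a
  property of chosen parameters, not an empirical finding.
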