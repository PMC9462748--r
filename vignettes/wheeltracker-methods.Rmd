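---
title: "Models and methods behind wheeltracker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wheeltracker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheeltracker)
```

`wheeltracker` models a one-pulse-per-revolution rotary-encoder tracker for
home-cage running wheels: a magnet on the wheel rim triggers a Hall-effect
sensor once per rotation, and a microcontroller reports cumulative counts
per sensor at a fixed refresh rate over a serial link. This vignette is the
package's own account of the models, conventions and numerical choices in
each stage, and of what the built-in simulator does and does not emulate.

## The measurement model

The only primitive the hardware observes is a rotation completion. One
count equals one rotation equals one magnet-path circumference of distance,
so every distance in the package is `count * circumference_cm`. Angled
running discs of the kind this models are 15–20 cm in diameter; because
the magnet's path radius, not the nominal wheel size, sets the conversion,
`wheel_geometry()` deliberately has **no default** — the experiment
configuration must state a diameter or circumference. Test fixtures use a
50 cm circumference (≈15.9 cm diameter) for round numbers.

Partial rotations are invisible to a single sensor: a mouse hopping on and
off the wheel can contribute up to one uncounted circumference per visit,
an error of centimetres against nightly totals of kilometres. The package
documents this rather than modelling it.

## Ground-truth simulation

**Robotic mode** (`simulate_robotic_run()`) reproduces a motorised
validation run: a piecewise-constant `speed_profile()` in which each
segment of duration `d` and rate `r` rev/s contributes `floor(d * r)`
rotations equally spaced at `1/r` s, and zero-rate segments are pauses.
The bundled `robotic_validation_profile()` is three 0.89 rev/s run
intervals (15, 15, 20 s) separated by pauses, 85 s in all; at a 50 cm
circumference the plateau linear speed is 44.5 cm/s. The rotation rate of
the original motorised test is not published, so this speed is used only
for self-consistency (recovered speed = configured speed), never as an
external reference value. Tests verify the rotation count against an
independent 1 ms time-stepping accumulator.

**Virtual-mouse mode** (`simulate_mouse_activity()`) is a rest/run bout
model, chosen as the simplest process that produces realistic nightly
distance curves; the source system makes no behavioural claim beyond
nocturnality, so the model is a package design choice:

- bout onsets follow a Poisson process whose rate switches with the
  light/dark schedule (`dark_bout_rate`, `light_bout_rate`, per hour),
  simulated by thinning at the maximum rate;
- bout durations are gamma (`bout_duration_mean_s`, shape
  `bout_duration_shape`) — positive and right-skewed, so most bouts are
  short with occasional long runs;
- each bout runs at a Gaussian linear speed (`run_speed_mean_cm_s`,
  `run_speed_sd_cm_s`), clipped below at 0 cm/s so rotation rates are
  never negative; rotations within a bout are equally spaced.

Laboratory mice run roughly 3–16 km per night. The defaults (20 bouts/h
dark, 1 bout/h light, 240 s mean bout, shape 2, 28 ± 6 cm/s) put the
expected nightly total mid-band: about 103 rest–run cycles fit into a 12 h
dark phase at ~6.7 km expected, and across seeds the simulated totals stay
well inside the band, with over 80 % of rotations in the dark. These are
the fixed study conditions of the package's tests, not tuning knobs.

What the generator emulates: phase-locked nocturnal bout structure,
realistic totals and speeds, reproducibility from a seed. What it does
not: individual animals within a group cage (the hardware cannot attribute
rotations to animals either), wheel inertia and coasting, ultradian
rhythms, or behavioural responses to interventions. Passing tests
therefore demonstrate correctness of the measurement-and-analysis chain on
plausible inputs, not behavioural fidelity of any particular mouse line.

## Acquisition emulation

`sense_rotations()` maps rotations to sensor triggers. The default
`sensor_config()` treats the sensor as exact — the physical validation
showed per-sensor counting to be essentially error-free — with a 50 ms
refractory period guarding against double triggers from magnet dither;
Gaussian timing jitter and Bernoulli missed triggers exist for robustness
testing only. With spacing above the refractory period the trigger times
equal the rotation times exactly.

`sample_counts()` quantizes time, not counts: sample `k` holds the number
of triggers with time ≤ `k × period`, the sample at `t = 0` is included,
and a trigger exactly on a sample instant belongs to that sample. Two
consequences:

- **Aliasing is bounded and transient.** A sampled count can lag the true
  rotation count by at most the rotations fitting into one sample period,
  and the books balance at the end of every interval — the transient
  between-sensor misalignment seen when a wheel's rotation period beats
  against a 0.25 s refresh rate, which disappears after a few rotations.
- **The recording window is whole periods.** A log holds
  `floor(duration / period) + 1` lines; a trigger after the final sample
  instant can never appear on any line, so `sample_counts()` rejects such
  streams instead of silently dropping counts. Callers choose a recording
  duration in whole periods covering the trace, and count conservation
  (final count = total triggers) is then exact.

The on-disk dialect is line-oriented text: `# key=value` headers (version,
ISO-8601 UTC wall start, sample period, sensor list, dialect, per-sensor
circumference), then one tab-separated line per sample of elapsed
milliseconds and per-sensor fields. Canonically the fields are lossless
integer **counts**, with circumference in the header; a `distance_cm`
dialect (fields to 0.1 cm) is provided for compatibility with loggers that
write distance directly, and parses back to counts by division and
rounding. Elapsed milliseconds avoid timezone arithmetic; the absolute
start lives only in the header.

## Parsing, resets and quality control

A cumulative column that decreases means the acquisition restarted
(counters re-zeroed after cage cleaning or sensor realignment). This is a
strict parse error naming the sample index — silent acceptance would
corrupt totals — but `parse_log(strict = FALSE)` admits the log so
`detect_counter_resets()` can splice it: each post-drop value is
interpreted as counts since the restart and re-based by the pre-drop
total, preserving every observed increment and restoring monotonicity.

`qc_scan()` flags, without ever mutating data: **flatlines** (zero count
increase for ≥ 2 h of dark time while at least one other sensor is
active — the signature of a wheel jammed by bedding; with no active
comparator the severity drops to a warning, since the room may simply
have been quiet), **counter resets**, and **missing sensors**. The 2 h
default window is a convention — no threshold is published for this
failure mode — chosen so a wheel blocked for a substantial part of a night
is caught while ordinary rest gaps (minutes) are not. Exclusion is
advisory: reports list candidate cages, and the statistics take an
explicit exclusion list, mirroring how a jammed cage is removed from an
analysis by explicit decision.

## Kinematics conventions

- Raw velocity at sample `k` is `(distance[k] − distance[k−1]) / period`;
  sample 0 has no preceding interval and is defined as 0. Velocities are
  never negative because counts are monotone.
- Smoothed velocity is a **trailing** (causal) moving average, default
  window 4 samples, matching both streaming acquisition and the 4-point
  average used when plotting wheel speed; partial windows average the
  samples available. During a pause the smoothed velocity reaches exactly
  0 once the window clears the last run sample.
- At one count per sample period resolution, instantaneous velocity is
  quantized in steps of `circumference / period`; the window-4 average is
  quantized at a quarter of that. Recovered plateau speeds are asserted
  within one quantization step, and interval averages much closer.
- Phase summaries attribute each sample's increment to the interval
  containing that sample, so per-interval distances sum to the series
  total exactly (telescoping).
- Bouts are maximal intervals with raw velocity ≥ 1 cm/s, merging rest
  gaps under 60 s; both thresholds are documented conventions (none are
  published for this system) and are override-able everywhere.
- Internally every distance is cm; reports convert to km (1 km = 1e5 cm).

## The paired permutation test

The before/after cage comparison uses the mean of per-cage differences as
its statistic — a deliberate choice of a mean-based non-parametric test
over a t-test (non-normal distances) and over rank-sum alternatives (the
scientific question is about means). Under the null the (before, after)
labels within each cage are exchangeable, so the null distribution is
built by sign-flipping each cage's difference:

- `permutation_test()` draws `B` (default 1000) independent Bernoulli(½)
  swap vectors — duplicates allowed — and recomputes the mean each time.
- `exact_sign_flip_test()` enumerates all `2^n` assignments (n ≤ 20) via
  iterative subset-sum doubling; it is the oracle the Monte-Carlo sampler
  is tested against (agreement within 3 binomial standard errors).
- Ties count as "at least as extreme" (conservative). Tie detection uses a
  relative tolerance of `1e-8` so that the identity assignment — whose
  null statistic equals the observed one by construction — always
  registers as a tie regardless of floating-point summation order.
- Sidedness defaults to `one_greater`: the motivating hypothesis
  (restriction increases running) is directional. `one_less` and `two`
  are available, and negating all differences swaps the one-sided
  p-values exactly.

Three p-value estimators are always computed: the empirical tail `k/B`;
the add-one estimator `(k+1)/(B+1)`, the default because it is never zero
and is the standard finite-sample-valid choice; and a kernel-density tail
area — the area under a Gaussian-kernel density of the null means beyond
the observed statistic, by trapezoidal integration with linear
interpolation at the cut, normalised by the total area and floored at
machine epsilon. The density variant exists because published p-values
from this style of test are sometimes tail areas of a fitted density
rather than tail proportions (they need not be integer multiples of
`1/B`); for a degenerate zero-variance null it falls back to the empirical
proportion. On Gaussian designs with ≥ 6 cages and `B ≥ 1000` it tracks
the empirical tail within 0.02.

`simulate_operating_characteristics()` wraps the test in a calibration
loop: per-cage differences are drawn Normal(effect, sd), designs are built
as `before = max(−d, 0)`, `after = max(d, 0)` (keeping distances
non-negative while the difference is exactly `d`), and the rejection rate
at α = 0.05 is reported. Under the null with 8 cages the exact test's
achievable p-values are multiples of 1/256, so the true size at 0.05 is
12/256 ≈ 0.047; the Monte-Carlo rejection rate is asserted within 3
binomial standard errors of 0.05. As noise vanishes with a positive
effect, the one-sided exact p approaches `2^{−n}`, so power reaches 1
whenever `2^{−n} ≤ α` — with 8 cages, always.

## Problem sizes and runtime choices

The test suite runs entirely on generated data: the 85 s validation
profile at 4 Hz (341 samples, five sensors), overnight fixtures sampled at
0.1 Hz to keep logs at a few thousand rows, 20-seed band checks for the
virtual mouse, 200 random traces for count conservation, Monte-Carlo runs
up to `B = 1e5` for oracle agreement, and 1000 replicates of `B = 1000`
for size calibration — sizes at which the whole suite completes in well
under a minute while leaving the statistical assertions comfortably
powered. `scripts/acceptance.R` re-runs the five-sensor mechanical
emulation from scratch and reports the final-count agreement percentage
and the maximum smoothed pause velocity.

## Known limitations

- No per-animal attribution in group cages; totals are per wheel.
- Partial rotations are uncounted (error ≤ one circumference per
  mount/dismount, centimetres against kilometres).
- The simulator's bout model is phenomenological; it is not fitted to any
  recorded dataset, and quantities that depend on real recordings (actual
  nightly totals of specific cohorts, their permutation p-values) require
  supplying those logs to the pipeline.
- The canonical log dialect is this package's own; logs from other capture
  software may need an adapter parser.
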