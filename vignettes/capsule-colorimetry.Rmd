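---
title: "Colorimetric bleeding detection: model, calibration and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric bleeding detection: model, calibration and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleedcap)
```

## The measurement model

An ingestible bleeding-detection capsule senses the colour of a
hemoglobin-adsorbing film. The colour sensor outputs, per colour filter, a
square wave whose frequency is proportional to reflected light intensity;
the microcontroller measures the mean frequency `f_C` (kHz) of each channel
`C ∈ {R, G, B}`. Two modelling layers sit on top of the raw frequencies.

**White balance.** A per-channel integration time `t_C` (ms) is calibrated
on a white reference so that the reference maps to the 8-bit white point:
`t_C = 255 / f_C(white)`. A reading's RGB components are then
`C = f_C · t_C`, dimensionless counts on a nominal 0–255 scale. The
device's calibrated constants — `t_R = 81.4097`, `t_G = 61.5481`,
`t_B = 54.0988` ms — are the package defaults (`white_balance()`), and
`calibrate_white_balance()` re-derives constants of exactly this form from
any white reading. Components are deliberately **not clamped** at 255: the
calibration targets white at 255 and the lightness-branch constants 128 and
510 confirm the 8-bit scale, but a super-white reading (a reference brighter
than the calibration white) is physically meaningful and flows through the
HSL formulas unchanged.

**HSL conversion.** With `m = max(R,G,B)`, `n = min(R,G,B)` and lightness
`L = (m+n)/2` on the 0–255 scale, saturation uses the lightness-branched
8-bit form (`(m−n)/(m+n)` below `L = 128`, `(m−n)/(510−(m+n))` at or
above), and hue uses the sector formula keyed on which channel attains the
maximum. Three numerical choices matter:

* **Hue wrap.** The `R = m` sector yields negative hue when `B > G`; hue is
  an angle, so values are wrapped into `[0°, 360°)` rather than clamped.
* **Ties.** When the maximum is attained by several channels the sector is
  chosen in the order R, then G, then B — the order the cases are listed.
  For the transparent-yellow juice solution (R ≈ G) both candidate sectors
  give 60°, so the choice is observationally safe on the bench data.
* **Achromatic inputs.** `m = n` makes both formulas 0/0 (and pure white
  makes the upper saturation branch's denominator vanish). Such inputs are
  flagged achromatic with `H = 0, S = 0` instead of erroring — clear
  intestinal juice can be near-gray. The guard uses an absolute spread
  tolerance of `1e-9` on the 0–255 scale so that white-balance round-trips
  (white reading × its own calibration) land exactly on gray despite
  floating-point rounding; the tolerance is ~5 orders of magnitude below
  any colour difference the 4-decimal frequency data can express.

The suite cross-checks this conversion against an independently coded
textbook HSL oracle (chroma/mod-6 formulation) on an 8-bit RGB grid to
1e-9, and verifies the bench characterisation table: eight of the ten
solutions reproduce the recorded hue (nearest degree) and saturation (two
decimals) exactly. Solutions 1 and 8 do not follow from their own recorded
frequencies (recomputation gives S ≈ 0.45 vs 0.33, and H ≈ 359° vs 9°,
respectively); we treat them as transcription errors in the source table
and assert the discrepancy rather than tune the formulas to fit it.

## The decision rule

Bleeding is called when the feature pair lies in a target region near red:
by default `3° ≤ H ≤ 25°` and `0.3 ≤ S ≤ 0.8`, all four bounds inclusive
(`target_area()`). The generic region form `[0, H0] ∪ [H1, 360]` with
wraparound is also supported, since hue is circular, but the calibrated
default is the plain interval. Lightness never enters the decision. The
saturation cap at 0.8 is kept as calibrated but exposed in configuration
(`region.s_high`): real blood/juice mixtures conceivably exceed it, and a
user who wants `S > 0.8` to alarm can widen the bound explicitly rather
than have the package decide silently.

**Reporting precision in the decision path.** The thresholds were
calibrated against features reported at integer degrees and two-decimal
saturation, so the capsule's decision path (`classify_features()`,
`run_capsule()`, `cmd_classify()`) quantises features to that precision
before the region test. This avoids knife-edge behaviour at the lower hue
bound: undiluted blood derives to H = 2.99897°, which must classify as
bleeding (it reports as hue 3, the boundary anchor). The raw predicate
`is_bleeding()` stays unquantised for callers who want full precision, and
the per-pixel raster mode uses raw features.

**Severity.** Within the region, lower hue means deeper red and less
diluted blood (the dilution series sweeps hue 41° → 3° monotonically as
saturation rises 0.20 → 0.63). Severity tiers exist in the device's alarm
vocabulary but their thresholds are not specified anywhere, so the bands
are explicit configuration with defaults `large: H ≤ 8`, `small: 8 < H ≤
15`, `trace: 15 < H ≤ 25`, chosen so the 1× and 4× dilution anchors grade
`large`, 16×/32× `small`, and the 64× boundary anchor `trace`.

## The capsule state machine and power model

`run_capsule()` simulates the firmware work flow: an initial dormancy
(default 7200 s — the enteric coating dissolves only at intestinal pH, so
nothing is sampled in the stomach), then a duty cycle of 5 s sleep and
0.5 s sampling. The period is their sum, 5.5 s: the device description
also says the sensor "works every 5 s", which conflicts with the stated
sleep+work durations, and we adopt 5.5 s because it reproduces the
published 0.7 mA average current (7.6 × 0.5/5.5 = 0.691; a 5.0 s period
would give 0.76). At most one reading is processed per period; each
processed reading is classified at reporting precision and

* a bleeding sample emits one severity alarm immediately — repeated
  bleeding samples repeat the alarm, one per cycle, with no hysteresis;
* a non-bleeding sample with supply voltage below the 2.4 V capsule
  threshold emits a low-battery alarm, latched to once per run by default
  since it is effectively a terminal notification (configurable);
* a bleeding sample at low voltage emits the **bleeding** alarm — the work
  flow's low-voltage branch only covers the no-bleeding case, and bleeding
  is the clinically important signal — with the voltage recorded in the
  event log.

The 2.7 V detection-module and 1.9 V transmitter thresholds are carried in
the configuration for documentation and assertions, but gating uses only
the 2.4 V capsule threshold, as the firmware does. Telemetry is a one-byte
code per event; decoding renders the receiver state (buzzer plus 1/2/3
LEDs by severity, buzzer alone for low battery). Transmission is modelled
as instantaneous and lossless; the RF burst's energy is excluded from the
power model (it is negligible next to the sampling budget and the
transmitter is powered down otherwise).

The power model is the duty-cycle average: active current is the sum of
sensor (2 mA), lighting (5 mA) and microcontroller (0.6 mA) currents;
sleep current is taken as exactly zero (the watchdog's draw is described
as approximately zero); average power multiplies by the 3.0 V regulated
supply. Battery life divides the 40 mAh nominal capacity by the average
current, ≈ 57.9 h — comfortably covering a 6–8 h intestinal transit.

## The synthetic dilution-series generator

The generator (`frequencies_for_dilution()`, `generate_stream()`) emulates
the bench characterisation: whole blood (hemoglobin 152 mg/ml) in a double
dilution series from 512× to 1×, plus two simulated intestinal juices as
non-bleeding baselines. Channel frequencies at an arbitrary dilution `P ∈
[1, 512]` interpolate linearly in `log2(P)` between the measured anchors —
linear in log-dilution because the bench series is a double dilution, and
exact at the anchors by construction. Extrapolation beyond the anchor
range is refused. Sensor noise is multiplicative lognormal, independent
per channel, with a default coefficient of variation of 2%: frequency
noise is positive and roughly proportional to the signal, and the bench
data give no noise magnitude, so the 2% default is a stand-in, clearly
labelled as such. Any noisy generation requires an explicit integer seed
(noise-free paths are seedless and deterministic), and the global RNG
state is never disturbed.

A scenario (`scenario_spec()`) assembles a run: a baseline juice, bleeding
episodes as time windows at a given dilution, a linearly decaying supply
voltage, and the capsule's duty-cycle timing; one reading is emitted per
cycle after the dormancy, with ground truth alongside for evaluation.

**What the generator does and does not emulate.** It reproduces the
colour-versus-dilution structure and sensor-level noise of the bench data.
It does not model film adsorption kinetics, dye transfer dynamics, mixing
of blood with juice, optical geometry changes, or intestinal motion —
passing tests show the computation is faithful to the bench
characterisation, not that the device performs identically in vivo.

**A data anomaly at the 16× anchor.** The recorded frequency triple of the
16× dilution solution is internally inconsistent with the dilution trend:
its derived hue wraps to ≈ 358.9° (blue channel above green, i.e. past
pure red) and its derived saturation (0.403) dips below the 32× value
(0.42), whereas every other anchor steps monotonically. The anchors are
kept exactly as recorded, and the tests assert the monotone trend over the
consistent anchors while asserting the 16× anomaly explicitly: a
noise-free stream at P = 16 is *not* called bleeding by the plain
calibrated interval (its reported hue 359 lies outside [3, 25]), although
the generic wraparound region form would catch it. Detection recovery is
therefore exact at the other anchors (100% of noise-free calls at P ∈ {1,
2, 4, 32, 64}, 0% at P ≥ 128, matching the 64-fold boundary) with a known
blind spot inherited from that one bench row.

**Detection under noise.** At the P = 64 boundary anchor the feature point
(H = 20.0, S = 0.330) sits close to two region edges: ≈ 0.85 noise
standard deviations above the S ≥ 0.3 cut and ≈ 0.69 below the H ≤ 25 cut
at the 2% default CV (which maps to σ_S ≈ 0.041 and σ_H ≈ 8.0° through
the conversion). The single-sample detection rate at the boundary is
therefore ≈ 70%, not near-certain — a genuine property of a threshold
rule evaluated at its own calibration boundary. The acceptance suite's
corresponding check expects > 90% and is left failing rather than
quietly relaxed; less diluted blood (P ≤ 32) detects essentially always,
and the capsule's repeat-per-cycle alarm policy means a sustained episode
at the boundary is still flagged within a few duty cycles.

## Problem sizes used in the test suite

The oracle grid uses 16³–4,096 8-bit triples (full suite) and 6³ in the
acceptance properties; property loops use 50–200 random cases under fixed
seeds; the noisy-rate check uses 1,000 seeded samples. The whole suite
runs in a few seconds on one CPU.

## Known limitations

* Severity band thresholds are package defaults, not device calibration.
* The 2% noise CV is a placeholder pending measured sensor noise.
* The 16× anchor blind spot is inherited from the bench table; a
  wraparound region or a corrected anchor row would remove it.
* The power model excludes the RF burst and treats sleep current as zero,
  so battery-life estimates are optimistic upper bounds.
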