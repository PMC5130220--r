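# bleedcap

Simulation and analysis toolkit for an ingestible capsule that detects
intestinal bleeding colorimetrically. The capsule carries a
hemoglobin-adsorbing film, a frequency-output colour sensor, and a
duty-cycled microcontroller: when intestinal juice dyes the film red, the
sensed colour moves into a calibrated hue/saturation region and the capsule
radios a severity-graded alarm to an external buzzer/LED receiver. bleedcap
reimplements that whole computation in software — sensor calibration,
colour conversion, the decision rule, the capsule state machine and its
power budget — plus a synthetic dilution-series generator so the pipeline
can be exercised and validated without hardware. It is aimed at biomedical
device engineers and researchers who want to study or extend the detection
logic off-device.

## The computation

The colour sensor reports, per colour filter, a mean square-wave frequency
`f_C` (kHz) proportional to reflected intensity. White-balance calibration
fixes per-channel integration times `t_C` (ms) so a white reference maps to
(255, 255, 255); a reading's RGB components are then

    C = f_C · t_C ,  C ∈ {R, G, B}

on a nominal 8-bit scale (not clamped). With `m = max(R,G,B)`,
`n = min(R,G,B)` and `L = (m+n)/2`, the film colour's HSL features are

    S = (m − n)/(m + n)            if L < 128
        (m − n)/(510 − (m + n))    otherwise

    H = 60·[0 + (G − B)/(m − n)]   if R = m      (wrapped into [0°, 360°))
        60·[2 + (B − R)/(m − n)]   if G = m
        60·[4 + (R − G)/(m − n)]   if B = m

Bleeding is called when (H, S) falls in the calibrated target region
3° ≤ H ≤ 25°, 0.3 ≤ S ≤ 0.8 (all bounds inclusive), and hue grades the
severity: lower hue means deeper red, i.e. less diluted blood. The capsule
sleeps for two hours after ingestion (while the enteric coating dissolves),
then samples on a 5 s sleep / 0.5 s work duty cycle; active current is
2 + 5 + 0.6 = 7.6 mA, giving a duty-cycle average of 7.6·0.5/5.5 ≈ 0.69 mA
and ≈ 2.1 mW at the 3.0 V supply.

## Worked example

Convert and classify the bench characterisation readings shipped with the
package (ten solutions: two simulated intestinal juices, then whole blood
diluted 512× down to undiluted):

```r
library(bleedcap)
fixture <- system.file("extdata", "table1_readings.csv", package = "bleedcap")
cmd_classify(fixture)
#>       t_s   h    s bleeding severity
#> 1  7200.0  47 0.45    FALSE     none
#> 2  7205.5  60 0.10    FALSE     none
#> 3  7211.0  41 0.20    FALSE     none
#> 4  7216.5  35 0.23    FALSE     none
#> 5  7222.0  28 0.27    FALSE     none
#> 6  7227.5  20 0.33     TRUE    trace
#> 7  7233.0  14 0.42     TRUE    small
#> 8  7238.5 359 0.40    FALSE     none
#> 9  7244.0   4 0.60     TRUE    large
#> 10 7249.5   3 0.63     TRUE    large
```

`h` and `s` are the derived colour features at reporting precision; the
dilution series sweeps from yellowish near-white (hue 41–60, weak
saturation) into deep red (hue 3, saturation 0.63), and the decision region
fires for the dilutions at or below 64-fold — the detection boundary, which
corresponds to a hemoglobin concentration of 152/64 ≈ 2.375 mg/ml. (Row 8,
the 16× dilution, is a known anomaly of the bench table: its recorded
frequencies put its hue at ~359°, off the dilution trend; see the methods
vignette.) The power report:

```r
cmd_power()
#> active current:  7.6 mA
#> average current: 0.7 mA
#> average power:   2.1 mW
#> battery life:    57.9 h
```

A synthetic scenario with a bleeding episode, run through the capsule state
machine:

```r
s <- cmd_synth(7400, episodes = data.frame(start_s = 7300, end_s = 7400,
                                           dilution = 64), noise_cv = 0)
sim <- cmd_simulate(s$readings)
head(sim$events, 2)
#>      t_s        kind payload_hex buzzer leds  h    s voltage_v
#> 1 7304.5 BLEED_TRACE          a1   TRUE    1 20 0.33         3
#> 2 7310.0 BLEED_TRACE          a1   TRUE    1 20 0.33         3
```

The same operations are available from a shell via the thin front-end
`inst/cli/bleedcap` (`convert`, `classify`, `simulate`, `synth`, `power`;
common flags `--config`, `--seed`, `--out`).

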