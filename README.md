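# reri

Tools for modelling how all-out running performance declines with event
duration, built around the **running energy reserve index (RERI)** — the
ratio of an athlete's maximal anaerobic to maximal aerobic speed
(RERI_spd = MAnS/MAS) or of the corresponding extrapolated oxygen demands
(RERI_E = E_MAnS/E_MAS). It is aimed at exercise physiologists and coaches
who want to predict race times across the 5 s – 25 min range from minimal
testing, and to profile athletes along the sprint–endurance continuum.

## The model

All-out speed (and the energy demand sustaining it) falls with duration *t*
as a rational function

    Spd(t) = (MAnS + b·t) / (1 + c·t)

with the analogous form for energy, E(t) = (E_MAnS + b_E·t)/(1 + c_E·t).
At *t* = 0 the curve equals MAnS, the maximal anaerobic speed; as
*t* → ∞ it approaches the aerobic plateau b/c = MAS. The curvature constant
*c* is remarkably stable across trained runners and is fixed at
**0.0185 s⁻¹** throughout, which makes the model linear in (MAnS, b): **two
all-out trials at distinct durations determine an athlete's entire
speed–duration curve exactly** (the two-trial procedure), and race times
for any distance follow by solving the quadratic
b·t² + (MAnS − c·d)·t − d = 0.

Around this core the package implements the full physiological derivation
chain:

- **Critical speed**: Spd = CS + ADC/(B + T_lim) fitted to exhaustive-run
  data; MAS is read off this hyperbola at the MAS duration.
- **Energetics**: submaximal VO₂–speed regression, extrapolated to MAS and
  MAnS for E_MAS / E_MAnS, and inverted at measured VO₂max for vVO₂max.
- **Signals**: breath-by-breath VO₂ resampling and smoothing,
  multi-exponential on-kinetics fitting, time-to-VO₂max detection (95%
  criterion), the five VO₂max attainment criteria, and the log–log
  lactate-threshold breakpoint with the υΔ50 / Vsub%95 speeds.
- **Synthetic athletes**: seeded generators with the published group
  structure (sprint / middle-distance / endurance-trained), used to
  validate every pipeline stage without needing raw athlete data.

## Worked example

Calibrate Sebastian Coe's speed–duration curve from his 400 m (47.05 s) and
mile (1609 m, 227.33 s) performances, then predict his 800 m:

```r
library(reri)
m <- two_trial_calibrate(run_trial(47.05, 400), run_trial(227.33, 1609))
coef(m)
#>       MAnS          b          c        MAS       RERI
#> 10.4359013  0.1161678  0.0185000  6.2793379  1.6619429
predict(m, distance = 800, actual_duration = 101.7)
#>   target_distance_m predicted_duration_s predicted_speed_ms actual_speed_ms
#> 1               800             103.8684           7.702056        7.866273
#>       ratio percent_error percent_error_time
#> 1 0.9791239      2.087611           2.132122
```

The calibration reproduces both input trials exactly (residuals at machine
precision) and predicts the 800 m within ~2.1% of the actual speed.
`MAnS` is the modelled maximal anaerobic speed (m/s), `MAS = b/c` the
maximal aerobic speed, and `RERI` their ratio — here 1.66, an
endurance-leaning middle-distance profile. `batch_predict()` summarises a
set of targets with the mean ± SD percent error and the R² of predicted
versus actual speeds; `write_report()` saves a table with both
full-precision and display-rounded columns.

A command-line front end is installed with the package
(`system.file("exec", "reri", package = "reri")`) with subcommands
`two-trial`, `fit`, `predict`, `mas`, `profile`, `kinetics`, `lt` and
`simulate`.

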