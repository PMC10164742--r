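---
title: "Methods: rational speed–duration modelling and the running energy reserve index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rational speed–duration modelling and the running energy reserve index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reri)
```

## The model and its assumptions

All-out running speed declines with event duration between two physiological
plateaus: the maximal anaerobic speed MAnS that can be expressed only for an
instant, and the maximal aerobic speed MAS that can be sustained at maximal
aerobic energy turnover. The package models this decline as a first-degree
rational function,

$$Spd(t) = \frac{MAnS + b\,t}{1 + c\,t}, \qquad
  E(t) = \frac{E_{MAnS} + b_E\,t}{1 + c_E\,t},$$

which equals MAnS at $t = 0$ and tends to $b/c$ as $t \to \infty$. The model
assumes (i) each trial is a genuinely all-out effort, so its mean speed sits
*on* the curve rather than below it; (ii) a single curvature constant $c$
describes the transition for all trained runners; and (iii) the anaerobic
reserve is positive, $b < MAnS \cdot c$, so the curve is strictly
decreasing. Fits violating (iii) are returned but flagged.

**Canonical parameterisation.** The package stores the triple
$(MAnS, b, c)$ but generates and interprets parameters through
$b = c \cdot MAS$, so that $Spd(t) = MAS\,(RERI_{spd} + c\,t)/(1 + c\,t)$
with $RERI_{spd} = MAnS/MAS$ the single shape ratio. The long-duration
asymptote is then exactly MAS. The alternative reading — that $b/c$ merely
approximates a long-sustainable speed related to MAS — is observationally
equivalent for fitting and prediction; the canonical choice is what the
derived `MAS` and `RERI` fields of a fit report, and nothing else in the
pipeline depends on it.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| $c$ (`fix_c`) | s⁻¹ | 0.0185 | curvature of the speed/energy decline; empirically stable across athletes, fixed everywhere, free fitting is opt-in (`free_c = TRUE`) |
| speed band | – | 0.90–1.40 × vVO₂max | admissible speeds for critical-speed points |
| 95 % criterion | – | 0.95 × VO₂max | primary criterion for time-to-VO₂max |
| APMHR | beats·min⁻¹ | 220 − age | age-predicted maximal heart rate in the five-criteria check |
| Vsub%95 offset | – | ±0.05 × vVO₂max | adjustment of υΔ50 so maximal aerobic energy is reached |
| MA window | s | 5 | moving-average width after 1 s resampling |

Fixing $c$ makes the model linear in $(MAnS, b)$: with $\ge 3$ trials the
fit is an exact linear least-squares problem on the transformed design
$[1/(1+ct),\; t/(1+ct)]$ (speed residuals are minimised exactly, no
iteration), and with exactly two trials the curve interpolates both — the
two-trial calibration, solved as a 2×2 linear system. Free-$c$ fits use
Levenberg–Marquardt on speed residuals, initialised at
$MAnS_0 = \max v$, $c_0 = 0.0185$, $b_0 = c_0 \min v$, with parameter
tolerance $10^{-10}$.

## Race-time inversion

A distance target $d$ requires solving $Spd(t)\,t = d$, i.e.
$b t^2 + (MAnS - c d)t - d = 0$. For $d > 0, b > 0$ the root product is
$-d/b < 0$, so exactly one root is positive and no tie-break is needed. The
implementation evaluates whichever of the two algebraically equivalent root
forms avoids subtracting nearly equal numbers ($2d/(B + \sqrt{B^2+4bd})$
when $B = MAnS - cd > 0$, the textbook form otherwise). With $b = 0$ the
equation is linear and has no solution when $MAnS \le c d$ — the model then
cannot cover the distance at any duration, and an error says so. Percent
errors are reported on speeds (with the time-based error alongside; the two
differ only through the predicted/actual ratio).

## The aerobic chain

MAS is derived, not assumed: the critical-speed hyperbola
$Spd = CS + ADC/(B + T_{lim})$ is fitted to exhaustive-run points
(Levenberg–Marquardt, speed residuals; starts $CS_0 = \min v$, $B_0 = 10$ s,
$ADC_0$ from the two extreme-duration points). $B$ has no stated
physiological interpretation and is treated as a free time offset. MAS is
the hyperbola evaluated at the MAS duration, which chains together the
time-to-exhaustion bookkeeping: time at VO₂max during the vVO₂max run
($T_{lim} - TA$), its conversion to the Vsub%95 speed (scaling by
$vVO_{2max}/Vsub\%95$), and the combination with the exhaustion time at
Vsub%95. The published combination is printed with a double negative
("minus negative"), which resolves to a sum; `mas_duration()` adopts
addition and exposes `sign = "subtract"` for the literal reading, since the
authoritative form lives in a companion report not available here.

## Signal processing choices

- **Resampling**: breath-by-breath data are linearly interpolated to a 1 s
  grid aligned to run start before the 5 s centred moving average. The
  interpolation scheme is not prescribed by convention; linear is the least
  committal and exactly preserves straight segments. Edge windows are
  truncated so constants pass unchanged and the filter is idempotent on
  constants.
- **Kinetics**: VO₂ on-kinetics are fitted as baseline plus two or three
  delayed exponential terms by weighted least squares. Weights default to
  uniform — the weighting named by the field's software is unspecified — with
  inverse-variance weights from the local residual spread as an option.
  Five deterministic multi-starts guard against local minima, and the
  three-term fit is additionally warm-started from the two-term solution
  with a zero third amplitude, which structurally guarantees the nested-model
  property (3-term SSE ≤ 2-term SSE). `n_terms = "auto"` selects by AICc.
- **Time to VO₂max** is read from the smoothed trace (robustness to breath
  noise; the raw-vs-smoothed choice is not prescribed), as the first grid
  second at or above 95 % of VO₂max. If the criterion is never met the
  result is `NA` carrying a `secondary_criteria_required` flag — the
  fallback criteria themselves are out of scope and deliberately not
  implemented.
- **Lactate threshold**: two straight segments on log(lactate)–log(speed),
  breakpoint chosen by exhaustive search over interior splits with at least
  3 points per segment, minimising pooled SSE; the threshold speed is the
  segment intersection. A split must improve the single-line SSE by a
  factor ≥ 1.5, otherwise no threshold is declared (a perfectly straight
  profile short-circuits to the same error).

## The synthetic-athlete generator

Generators exist so every stage is testable without raw athlete data. They
emulate the published group structure of trained runners — sprint-trained
(MAS 3.64 ± 0.17, MAnS 9.86 ± 0.61 m/s), middle-distance (4.13 ± 0.22,
9.07 ± 0.19) and endurance-trained (4.70 ± 0.44, 8.17 ± 0.38) — with all
normals truncated at ±3 SD to exclude non-physical profiles.

The default draw is **(MAS, RERI_spd)** with MAnS formed as their product,
rather than independent MAS and MAnS draws. The reason is statistical
fidelity: the published within-group dispersion of RERI_spd (SD 0.11–0.14)
is the dispersion of *individual ratios*, and speed maxima are positively
correlated within a training group; independent draws would inflate the
ratio's SD to ~0.13–0.18 by the delta method and misstate the group
overlap that the classifier faces. `method = "independent"` provides the
uncorrelated variant for sensitivity checks. Energy values come from a
per-athlete submaximal regression whose intercept is drawn near zero, so
RERI_E tracks RERI_spd tightly — the near-identity of the two indices in
trained runners is a finding the generator mirrors, and its exact limit
(zero intercept ⇒ equality to machine precision) is asserted in the tests.

What the generator does **not** emulate: day-to-day biological variability,
pacing and tactical effects in longer races, environmental conditions, and
any true nonlinearity of the oxygen cost of speed at sprint velocities
(the linear extrapolation to MAnS is a modelling idealisation). Passing
tests therefore demonstrate internal consistency and correct recovery under
the stated noise models, not field validity on real athletes.

Group classification is nearest-centroid on RERI_spd (centroids 2.71, 2.20,
1.75); exact midpoint ties break toward the smaller centroid, so 2.455
labels as MD. Classification uses the speed index only by default because
the track-only two-trial pathway yields no energy measurements.

## Numerical conventions and problem sizes

Internal energy units are ml·kg⁻¹·s⁻¹; per-minute file inputs are converted
at the I/O boundary (exact factor 60). One mile is taken as 1609 m. Display
rounding (speeds 1 dp, ratios 2 dp, errors 1 dp) is applied only in
reports; internal values are never rounded. Seeded generators save and
restore the global RNG state, so they are pure functions of their seed.

The validation suite exercises: two-trial exactness over 1000 random
parameter sets (interpolation residuals ≤ 10⁻¹²), the inversion identity
over 10⁴ random (parameter, distance) pairs (≤ 10⁻⁶ relative), noise-free
recovery of both the rational model and the hyperbola (≤ 10⁻⁸ relative),
seeded noisy recovery (speed noise σ = 0.05 m/s, hyperbola noise σ = 0.03
m/s, VO₂ noise σ = 1 ml·kg⁻¹·min⁻¹), the full kinetics-to-MAS chain
(within 2 % of ground truth at those noise levels), and nearest-centroid
separation of a 300-athlete simulated cohort (≥ 95 % agreement). These
sizes keep the whole suite in the tens of seconds while leaving the
stochastic margins wide.

## Known limitations

- The rational model is calibrated for efforts of roughly 5 s to 25 min;
  ultra-endurance durations drift below the MAS plateau (fatigue,
  thermoregulation) and are outside its domain.
- The two-trial calibration is exact but therefore noise-sensitive: errors
  in either trial propagate directly into (MAnS, b). Trials far apart in
  duration (one sprint-like, one ≥ 90 s) condition the solve well.
- Fixing c at 0.0185 s⁻¹ trades a small bias for large variance reduction;
  athletes with atypical curvature are served by `free_c = TRUE` with ≥ 3
  trials.
- The secondary criteria for time-to-VO₂max when the 95 % criterion fails
  are not implemented; callers receive an explicit flag instead.
- MAS depends on the critical-speed fit's extrapolation beyond the measured
  durations; its error is dominated by the CS estimate, not by the
  kinetics-derived MAS duration (the hyperbola is flat there).
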