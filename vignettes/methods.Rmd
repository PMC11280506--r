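---
title: "Calibrating infant activity-intensity cut-points from ankle accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating infant activity-intensity cut-points from ankle accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(legacc)
```

## The measurement problem

Pre-ambulatory infants produce physical activity almost entirely through
limb movement in supine, so ankle-worn tri-axial accelerometers are a
natural instrument — but the intensity cut-points validated for walking
children do not transfer. `legacc` implements a calibration pipeline that
maps raw ankle accelerometry to three intensity classes (sedentary,
light, moderate-to-vigorous), using human video coding of the same
session as the gold standard. The video coding assigns every moment to
one of the three classes in intervals of at least 2 s; the accelerometer
side summarizes non-overlapping 2-s epochs by a scalar "derived
quantity" and classifies each epoch by two cut-points.

## Signal model and preprocessing

The raw signal per leg is a uniformly sampled tri-axial series
$(a_{x,i}, a_{y,i}, a_{z,i})$ in m/s² (20 Hz by default). The pipeline
assumes the sensor measures gravity plus movement plus noise, and that
sensor orientation changes slowly relative to movement dynamics.

**Magnitude.** $a_{M,i} = \sqrt{a_{x,i}^2 + a_{y,i}^2 + a_{z,i}^2}$ is
orientation-free, so no attitude estimation is needed.

**Gravity baseline.** Because the magnitude of a resting sensor equals
the local gravity norm, $a_G$ is estimated as the mean of $a_M$ over
*static segments*: windows of 10 samples (0.5 s) whose range
(max − min) is at most 0.1 m/s² (≈ 10 mg, comparable to stillness
thresholds used in large actigraphy studies). The scan slides one
sample at a time — the most inclusive reading of "continuous regions" —
and overlapping qualifying windows are merged into maximal runs. The
comparison is `<=` at the threshold. If a recording contains no static
segment, $a_G$ falls back to the median of the series, which is robust
as long as the infant is still more often than not at the
sample level. The estimate is computed per sensor per session, since
calibration offsets differ between sensors and days.

**Gravity removal.** $a_{IND,i} = a_{M,i} - a_G$. Values can be
negative (movement opposing gravity); no clipping is applied, because
the epoch features rectify later.

**Leg-length adjustment.** For the same angular limb movement, a longer
leg produces a proportionally larger linear acceleration at the ankle.
The signal is therefore rescaled to a 26.5 cm baseline leg length (the
median rump–sole length of 3–5-month-old infants):
$a_{ADJ,i} = a_{IND,i} \cdot 26.5 / \ell$, with $\ell$ the subject's
thigh + shank length in cm. The direction of this ratio matters and is
easy to get wrong: scaling *down* for longer legs is the only direction
that removes the mechanical-advantage effect, so it is the default;
`adjust_leg_length(direction = "leg_over_baseline")` exposes the inverse
reading for sensitivity analysis.

## Epoch features

Within each gold-standard interval, valid windows of 2 s tile the
interval from its start; a trailing remainder shorter than 2 s is
discarded so every window is wholly contained in one intensity region.
Two derived quantities are computed per window and leg:

* $c_A = \sum_i |a_{ADJ,i}|\,\Delta t$ — area under the
  acceleration–time curve (m/s), the continuous-units analogue of
  classic actigraphy counts;
* $c_J = \sum_i |j_i|\,\Delta t$ with
  $j_i = (a_{ADJ,i} - a_{ADJ,i-1})/\Delta t$ — area under the jerk–time
  curve (m/s²), sensitive to changes in force rather than its level.

Numerical choices, each fixed once and tested:

* **Rectification.** Absolute values are integrated. A signed integral
  of a zero-mean oscillation would cancel to ≈ 0 and carry no intensity
  information; rectified areas are non-negative and scale linearly with
  signal amplitude. The signed variant stays available behind
  `rectify = FALSE`.
* **Riemann sum, not trapezoid.** The feature is defined as the plain
  left-Riemann sum matching the printed actigraphy convention; at 20 Hz
  over 40-sample windows the difference is negligible against class
  separations.
* **Jerk across window boundaries.** Jerk is differenced once on the
  continuous recording (the sample preceding a window contributes to
  its first jerk value); only the very first sample of a recording has
  no predecessor and gets $j_1 = 0$. Restarting the difference per
  window would silently delete one sample of signal per window.
* **Classification boundaries.** `classify_epoch()` is left-closed
  upward: a value exactly at a cut-point takes the *higher* class. Any
  single convention works; this one keeps classification monotone and
  is asserted in the tests.
* **Annotation alignment.** Interval boundaries are snapped to the
  nearest sample instant with exact half-sample ties resolved toward
  the earlier sample. Whether annotation clocks are relative to video
  start or sensor sync is study-specific, so the clock offset is an
  explicit input parameter rather than something the package guesses.

## Cut-point calibration

Calibration pools all training subjects' epochs unweighted and runs a
two-stage grid search.

**Grids.** Candidates step 0.01 m/s for acceleration areas and
0.1 m/s² for jerk areas, from 0 to the largest observed $c_{TOTAL}$.
These steps resolve the last printed digit of the packaged cut-points
(0.300–2.60 m/s, 7.00–56.0 m/s²) while keeping the search exhaustive
and deterministic.

**Costs.** The printed cost expressions are raw differences
(TP method) and signed relative deviations (PAP method); both are
minimized in absolute value, because the raw forms have no interior
minimum — the verbal description of the methods ("too low … too high …
just right") identifies a crossing point, and $|{\cdot}|$ is the
function whose minimum sits at that crossing.

**Tie-breaking.** The primary stage takes the *smallest* candidate
attaining the minimal cost. The secondary stage takes the *largest*.
The asymmetry is deliberate: when the classes separate cleanly the
primary TP rates are both 100% at the optimum, so the frozen reference
rate `TP_FIXED` is exactly 100 and the secondary TP cost is zero on an
entire plateau from the primary cut-point up to the smallest MV epoch
value. The smallest candidate on that plateau would collapse the light
class to nothing; the largest sits where $TP_{MV}$ is about to fall
below `TP_FIXED` — the crossing point the method describes — and makes
both calibration methods agree (within one grid step) on separable
data. On overlapping (realistic) data the plateaus are narrow and the
choice is immaterial.

**Constraint.** The secondary search is restricted to candidates at or
above the primary cut-point, so fitted sets always satisfy
$t_{sed/active} \le t_{light/MV}$.

## Evaluation metrics

`evaluate_epochs()` recomputes predictions from the cut-points (never
reusing optimizer internals, since validation uses held-out subjects)
and tabulates gold × predicted counts for the primary (2 × 2,
ACTIVE = LIGHT ∪ MV) or secondary (3 × 3) stage. Per class: TP rate
(diagonal over gold row total), TN rate (complement epochs predicted
outside the class), and predicted/gold activity proportions (column/row
totals over the grand total). Overall ratings: MTPR, the minimum TP
rate over SED and ACTIVE (primary) or SED and MV (secondary — light is
deliberately excluded because MV classification is prioritized), and
PMR, 100 minus the total absolute gold-vs-predicted proportion
deviation. All rates are carried at full precision and rounded only for
display (one decimal); rounding intermediate rates before deriving
MTPR/PMR produces 0.1–0.2-point inconsistencies, which is visible in
published tables of this kind and is exactly what the package's
cross-check tests tolerate and nothing more.

## The synthetic-session generator

Real infant recordings with synchronized video coding are not publicly
distributable, so `generate_session()` provides seeded sessions with
the statistical structure the pipeline assumes. Defaults were fixed
once to mirror the study conditions: 20 Hz sampling; 330-s sessions
(the study's aligned sessions averaged ≈ 5.7 min, range 2.7–8.5); bouts
of 2–12 s (gold epochs are at least 2 s); bout class mix 0.41 / 0.19 /
0.40 (the gold proportions of the study's validation tables); a ≥ 2-s
still prefix so gravity is estimable; gravity 9.81 m/s²; axis noise sd
0.05 m/s²; and per-bout sinusoid-burst movement at 1–4 Hz (below the
10 Hz Nyquist) with class amplitudes 0.10 / 0.60 / 2.00 m/s². The
amplitudes were chosen from the closed forms
$c_A \approx (4/\pi) A$ per leg per 2-s window and
$c_J \approx 8 A f$, so that both-legs $c_A$ bands straddle the
packaged 1.0 / 2.6 m/s cut-points; per-bout lognormal amplitude jitter
(sdlog 0.2) spreads the bands. Movement is directed along the gravity
vector, which makes the magnitude signal exactly gravity + movement and
keeps the generated class bands controllable; a slow sinusoidal tilt
(0.1 rad) exercises the orientation-drift assumption.

What the generator does **not** emulate: intermittent within-bout
movement (real "light" epochs mix moving and still moments), caregiver
contact artifacts, sensor saturation, and class-overlapping amplitude
distributions as broad as real infant behavior. Consequently the
synthetic classes are much more separable than real ones: recovery
tests reaching 100% MTPR/PMR demonstrate the *correctness of the
pipeline arithmetic and the optimizer*, not the field performance of
the cut-points, which on real validation data sits near 70–80%.

The parameter-recovery experiments use a deliberately separable
configuration (no amplitude jitter, 2–2.5 Hz frequency band, noise sd
0.005): with disjoint per-class bands the feasible separating
cut-points form known gaps, so recovery "within one grid step of the
band edge" is a sharp, assertable property. The frequency band is
narrowed because $c_J \propto A f$: at 1–4 Hz the light and MV jerk
bands would overlap even with disjoint amplitudes.

## Problem sizes and runtime

The test suite runs on sessions of 30–900 s (one 10-min session for the
recovery experiment) and oracle comparisons on hundreds of randomized
small instances; the acceptance script simulates ten 330-s subjects.
These sizes give stable statistics (≈ 1200 training epochs) while the
full suite completes in well under a minute.

## Known limitations

* Single-sensor-position design: ankle only; arm or head sensors would
  need their own calibration.
* The gravity baseline is a session constant; very long recordings with
  temperature drift would need a windowed baseline.
* The two-stage search optimizes each cut-point conditionally, not the
  pair jointly; this matches the method being implemented but can be
  suboptimal for costs with interacting stages.
* Degenerate label distributions (a missing gold class) are rejected
  rather than imputed; calibration needs all three classes present in
  the pooled training epochs.
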