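---
title: "From sensor signals to movement asymmetry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sensor signals to movement asymmetry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungesym)
library(dplyr)
```

## The problem

Quantitative lameness assessment in horses rests on left/right differences
in the vertical motion of upper-body landmarks during trot. A five-sensor
inertial system (poll, withers, sacrum, left and right tuber coxae,
sampling at 100 Hz) yields, per assessment condition, eleven signed
asymmetry indices in millimetres: differences in displacement minima,
maxima and upward amplitudes for head (`HDmin`, `HDmax`, `HDup`), withers
(`WD*`) and pelvis (`PD*`), the hip hike difference `HHD` (left tuber
coxae upward amplitude during right-hind stance minus the mirror-image
quantity) and the tuber coxae range-of-motion difference `RD`.

On the lunge, the centripetal force balance makes the horse lean into the
circle by `atan(v^2 / (g r))` degrees, and that lean adds circle-induced
asymmetry on top of whatever the horse shows on the straight. Because the
lean mirrors between the left and right rein at equal speed, averaging the
two reins should cancel the circle term - the central idea this package
implements and probes: sign-normalize every parameter against the horse's
preexisting straight-line asymmetry, relabel reins as inside/outside,
combine them into average-rein values, and compare straight-line,
individual-rein and average-rein measurements with agreement statistics
and random-intercept mixed models.

## The synthetic data generator

No raw study recordings are distributed, so the package carries a
first-class simulator with two levels.

**Signal level** (`simulate_landmark_signal()`, `simulate_trial()`).
Vertical displacement of each landmark is a two-harmonic waveform per
stride,

$$z(\theta) = a_0 + a_1\cos\theta + b_1\sin\theta - A_2\cos 2\theta,$$

with $\theta$ the stride phase: the $2\theta$ term is the dominant
two-per-stride trot oscillation, the $\theta$ term carries the left/right
asymmetry (midline landmarks) or the once-per-stride hip hike (tuber
coxae). The four coefficients are solved by Newton iteration so that the
waveform's four extrema per stride equal the prescribed per-step values
*exactly*; because the extremum phases satisfy $z'(\theta^*)=0$, the
Jacobian of the extremum values with respect to the coefficients is simply
the design matrix at the current extremum phases, and the iteration
converges to machine precision in a few steps. Injected quantities are
therefore exact ground truth: `asym_min`/`asym_max` per midline landmark,
`hike_diff` and `rom_diff` for the tuber coxae. The upward-amplitude
asymmetry is structurally `asym_max - asym_min` (a maximum minus its
immediately preceding minimum), exactly as for the real indices, so it is
derived, not free.

The waveform being band-limited to twice the stride frequency is a
deliberate choice: earlier piecewise-connector designs placed kink
harmonics above the Nyquist frequency of the 100 Hz sensor, which alias
back onto the stride frequency and are amplified by $1/\omega^2$ during
double integration - a distortion of the *ground truth*, not of the
method. Real trot displacement does contain energy above the second
harmonic; what that means for the tests is discussed under Limitations.

The accelerometer channel is the analytic second derivative plus gravity,
expressed in a sensor frame tilted by a fixed known rotation (roll 3,
pitch -5, yaw 15 degrees). Sensor noise (`noise_sd`, default 0; 2 mm in
the calibration scenarios) is *displacement-referred*: a 20 Hz
band-limited noise floor with RMS `noise_sd` millimetres, injected into
the acceleration channel as its exact second difference so that double
integration reproduces it. This makes the noise level interpretable
against the millimetre-scale indices; it does not emulate the coloured
low-frequency drift of real inertial sensors (the high-pass stage exists
for exactly that, but the tests do not exercise realistic drift spectra).

Stride-to-stride timing jitter is uniform within a fraction
`stride_time_jitter` of the stride time (default 0.03; steady-state trot
in sound horses has a stride-time coefficient of variation of about
2-3%). One integer seed drives everything; per-landmark noise streams are
split deterministically from it, and all landmarks of a trial share one
stride schedule, so single-landmark simulations compose into coherent
trials. Lunging is modelled by `apply_circle_modulation()`: every injected
asymmetry is shifted by `lean_gain x body_lean_angle(v, r)` millimetres
toward the inside of the circle. The lean-to-asymmetry map is linear
because only its mirror symmetry between reins matters downstream; the
literature reports the association but no functional form. `lean_gain`
defaults to 0.8 mm/deg, which at 3 vs 4 m/s on a 7.5 m circle produces
individual-rein speed shifts of roughly 4 mm - the magnitude reported for
speed-affected parameters - and is a free parameter, not an estimate of
any published relation.

**Condition level** (`simulate_study()`). One record per horse x surface x
speed x direction with, per parameter: baseline + horse intercept
(`N(0, horse_sd)`) + surface shift + speed shift + the mirror lean term
(`+delta` left rein, `-delta` right rein) + residual. Defaults emulate the
published study design: 27 horses, up to 12 assessments each, baselines at
the reported straight-line means of the 11 parameters, and a stride-time
model shaped like the reported estimated marginal means (grand mean
772 ms, fast/slow 753/791 ms, hard/soft 765/779 ms, straight/left/right
747/786/783 ms). `horse_sd = 6` mm and `residual_sd = 2.5` mm are chosen
once to be of the order of the reported between-horse spread and
intra-horse straight-line variation.

## The kinematic chain

`process_trial()` runs, per condition:

1. **Frame rotation** (`rotate_to_horse_frame()`): the per-sample Euler
   rotation into a right-handed, gravity-aligned frame (x forward, z up,
   y to the left; positive pitch is nose-up), keeping the vertical
   component and subtracting 9.81 m/s^2.
2. **Double integration** (`integrate_to_displacement()`): zero-phase
   fourth-order Butterworth high-pass (an order-2 filter run forward and
   backward) on acceleration and again on velocity, cumulative trapezoid
   integration with a symmetric (-1, 14, -1)/12 correction kernel that
   cancels the trapezoid's $-\theta^2/12$ spectral bias to fourth order.
   The high-pass cutoff is a quarter of the stride frequency: at half the
   stride frequency (an alternative sometimes used) the net amplitude loss
   at the stride frequency is ~11%, which would bias every index
   multiplicatively; at a quarter it is under 1%.
3. **Tone-band smoothing**: the displacement is reduced to two zero-phase
   pass bands centred on the stride frequency and its double (geometric
   edge factors 1.2 and 1.15). All eleven indices are defined by the first
   two stride harmonics, so this is matched filtering: wide-band sensor
   noise is rejected without touching the feature content. Stride
   segmentation uses the broadband displacement instead
   (`tone_bands = FALSE`), because heavy stride-time jitter spreads signal
   energy outside narrow bands.
4. **Stride segmentation** (`segment_strides()`): the dominant oscillation
   period comes from the first autocorrelation peak above 0.5 between 0.2
   and 0.8 s (trot midline landmarks oscillate twice per stride, so the
   stride period is twice that); boundaries are displacement minima found
   by phase-locked tracking - anchor at the deepest trough (earliest
   within 0.25 mm, so symmetric gaits segment deterministically), then
   walk outward accepting the deepest minimum in a jitter-tolerant window
   of 0.7-1.35 periods, with a skip window for a single missed trough.
   Strides deviating more than 25% from the running-median stride time are
   discarded as non-steady-state; fewer than `min_strides` (default 15)
   retained strides is an error. The published protocol aimed for 25-30
   strides; 15 is a hard floor below which medians get unstable.
5. **Feature extraction** (`extract_stride_features()`): per stride the
   four midline extrema are located in quarter-stride search windows
   (robust to a few samples of boundary jitter between landmarks). Minima
   sit exactly on stance transitions, so each minimum inherits the
   step-side label of its (mid-step, reliably labelled) maximum. Tuber
   coxae: the hike maximum is the highest point during the step matching
   the landmark's own side (its contralateral hind stance), and the hike
   amplitude is measured from the stride minimum - a symmetric definition
   under which noise-induced extremum bias cancels in `HHD`. Step sides
   come from simulator ground truth in tests, or from tuber coxae phase
   (`attribute_steps()`) on unlabeled data.
6. **Indices and medians** (`stride_asymmetry()`, `condition_summary()`):
   all indices are left-associated minus right-associated quantities; a
   condition is summarized by per-stride medians plus the median stride
   time.

The first and last 1.5 stride periods of each record are excluded from
feature extraction to keep filter transients out.

## Normalization and average rein

Normalization is per horse *and per parameter*: if the mean straight-line
value of a parameter is negative, all values of that parameter for that
horse are inverted, so positive always means "same direction as the
preexisting asymmetry". An exact-zero mean (possible only in degenerate
synthetic data) counts as positive, with a warning. The preexisting side
(left/right) follows directly from the sign convention of the indices;
since inside/outside relabeling and everything downstream depend only on
consistency of that convention, no external force-asymmetry table is
needed. Because sides are per-parameter, the normalized dataset is a long
(tidy) table keyed by horse x surface x speed x rein x parameter.
`average_rein()` adds the arithmetic mean of matched inside/outside pairs;
conditions missing one rein contribute no average row. Averaging uses the
per-condition medians, not pooled strides, mirroring how conditions are
tabulated before combination.

## Statistics

* `describe_asymmetry()` and `intra_horse_sd()`: straight-line
  descriptives (mean, SD, mean absolute value, min, max, left/right side
  counts) and the pooled SD of deviations from each horse's straight-line
  mean, for horses with at least two straight conditions. All SDs use the
  n-1 denominator.
* `limits_of_agreement()`: Bland-Altman bias, SD and 2 x SD band of
  straight-minus-average differences over matched conditions.
* `straight_vs_rein_trends()` / `linear_trend()`: OLS slope, intercept and
  R^2 of average-, inside- and outside-rein values against matched
  straight-line values; slopes below 1 mean reduced asymmetry on the rein.
* `fit_gait_model()`: REML random-intercept fits
  (`value ~ fixed + (1 | horse)`, lme4). Per-factor p-values are Wald F
  tests with residual degrees of freedom (observations minus fixed-effect
  columns) - the degrees-of-freedom method is encapsulated precisely
  because the original software's choice is not documented; Satterthwaite
  or Kenward-Roger machinery is deliberately out of scope. Estimated
  marginal means are model predictions averaged over a balanced grid of
  the other fixed factors (the classical definition; cross-checked against
  emmeans in the test suite). Singular random-effect fits and
  non-convergence are flagged, never silent; `drop_singular_random = TRUE`
  refits as a fixed-effects model on request. Residuals are exposed and
  `autoplot()` draws the inspection histogram.
* `pairwise_direction_comparisons()`: all pairwise contrasts of one
  factor's marginal means, Bonferroni-adjusted by the number of pairs
  (`min(1, p * m)` - adjusted p-values rather than an adjusted alpha, so
  significance reads against the usual 0.05).

## Numerical choices, degenerate inputs, tie-breaks

* Constant response: the model short-circuits to p = 1 with equal
  marginal means instead of fitting.
* Constant displacement: segmentation raises a "no cycles" error naming
  the problem; non-finite acceleration names the first offending index.
* Exact-zero preexisting mean: sign +1, warning.
* Symmetric gait: segmentation anchors at the earliest near-deepest
  trough, making the boundary phase an arbitrary but deterministic choice
  (on perfectly symmetric signals stride and step are indistinguishable in
  principle; only stride-level quantities are reported).
* The two-harmonic coefficient solver refuses target extrema it cannot
  represent (error, not silent clipping).

## Problem sizes in the tests

The test suite simulates trials of about 30 retained strides (27 s at
100 Hz), studies of 6-10 horses for invariants, 100 studies of 8 horses
for the individual-vs-average speed-significance contrast, and 200
replicates of 30 horses for mixed-model calibration (bias of the surface
effect under truth 2 mm; empirical type-I error of a null speed effect at
alpha 0.05). These sizes give stable Monte Carlo estimates while keeping
the default run in minutes.

## Limitations

* The generator is band-limited to two stride harmonics and the feature
  filter matches it. Real trot displacement carries higher harmonics and
  asymmetric waveform shapes; passing tests show the chain recovers
  asymmetries injected *at the extremum level under this signal model*,
  not that it is calibrated against optical motion capture.
* Sensor noise is white within 20 Hz and displacement-referred; real IMU
  error is dominated by coloured drift and orientation error, which are
  not simulated (the magnetometer is out of scope entirely).
* Only vertical motion is simulated; the rotation stage is exercised with
  constant mounting orientations, not dynamic trunk rotation.
* The left/right attribution of each parameter follows one internal
  left-minus-right convention. It is consistent across the whole pipeline
  - which is all the normalization, averaging and models require - but a
  particular horse's "left-sided" label is not guaranteed to match the
  convention of any specific commercial system.
* Speed is represented by category (with stride time as its proxy, as in
  the stride-time model); no continuous speed measurement is modelled.

## A short worked example

```{r example, fig.width = 6, fig.height = 4}
records <- simulate_study(study_effects(n_horses = 8), seed = 42)
norm <- normalize_asymmetry(records, quiet = TRUE)
tidy(limits_of_agreement(norm)) |> head(4)

fits <- fit_asymmetry_models(norm, directions = "inside",
                             fixed = c("surface", "speed"))
fits |> select(parameter, factor, p_value, emm_abs_diff) |> head(6)

autoplot(straight_vs_rein_trends(norm))
```
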