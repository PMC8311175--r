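# lungesym

Movement-asymmetry gait analysis for trotting horses assessed in hand and
on the lunge.

During the equine lameness exam, horses are trotted on the straight and in
circles ("on the lunge", typically a 15 m circle, each travel direction a
"rein"). Inertial sensors on five body landmarks — poll, withers, sacrum
and both tubera coxarum, sampled at 100 Hz — quantify left/right
differences in vertical motion. The difficulty is that circling itself
induces asymmetry: the centripetal force balance makes the horse lean
inward by

    lean angle = atan(v² / (g·r))     [v speed, r circle radius, g = 9.81 m/s²]

and measured asymmetry grows with that lean. Because the lean mirrors
between reins at equal speed, averaging the two reins should cancel the
circle-induced part and expose the horse's own asymmetry.

`lungesym` implements the full analysis chain:

* **Kinematics** — rotation of tri-axial accelerations into a
  gravity-aligned horse frame, drift-corrected double integration to
  vertical displacement, autocorrelation-based stride segmentation, and
  per-stride feature extraction.
* **Indices** — the eleven signed asymmetry measures (mm): `HDmin`,
  `HDmax`, `HDup` (head), `WD*` (withers), `PD*` (pelvis), plus the hip
  hike difference `HHD` and the tuber coxae range-of-motion difference
  `RD`, summarized per condition by stride medians.
* **Normalization** — per horse and parameter, sign inversion against the
  preexisting straight-line asymmetry; inside/outside rein relabeling;
  average-rein combination of matched rein pairs.
* **Statistics** — straight-line descriptives and intra-horse SD,
  straight-vs-rein trend fits, Bland–Altman limits of agreement, REML
  random-intercept mixed models (`value ~ surface + speed (+ direction) +
  (1 | horse)`) with balanced-grid estimated marginal means and
  Bonferroni-adjusted pairwise comparisons.
* **Synthetic data** — a tested generator of five-landmark trot signals
  with exactly known injected asymmetries, circle-induced lean, horse
  random effects and surface/speed effects, so the whole chain is
  verifiable without instrumented horses.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` for fitted objects, `autoplot()` for result types.

## Worked example

Simulate a trial with known asymmetries (HDmin 6 mm, PDmin 4 mm, HHD
5 mm, 2 mm sensor noise) and push it through the kinematic chain:

```r
library(lungesym)

tp <- trot_params(duration = 27, noise_sd = 2,
                  asym_min = c(poll = 6, withers = 0, sacrum = 4),
                  hike_diff = 5)
trial <- simulate_trial(tp, seed = 1)
process_trial(trial)
#> <gait_processed> 32 strides (0 discarded, 0 incomplete), stride freq 1.389 Hz
#> # A tibble: 1 × 13
#>   HDmin  HDmax  HDup  WDmin  WDmax   WDup PDmin PDmax  PDup   HHD     RD
#>   <dbl>  <dbl> <dbl>  <dbl>  <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1  5.75 -0.202 -5.74 -0.147 -0.270 0.0246  3.77 0.392 -3.48  4.49 -0.271
```

The injected 6 / 4 / 5 mm come back as 5.75 / 3.77 / 4.49 mm from noisy
signals — each within the expected sub-millimetre error of a 32-stride
median. (`HDup = HDmax − HDmin` by construction, hence ≈ −5.7.)

Condition-level analysis of a simulated 8-horse study:

```r
rec  <- simulate_study(study_effects(n_horses = 8), seed = 42)
norm <- normalize_asymmetry(rec, quiet = TRUE)

tidy(limits_of_agreement(norm))[1:3, ]
#> # A tibble: 3 × 5
#>   parameter   bias    sd  band n_pairs
#> 1 HDmin      0.531  3.00  5.99      32
#> 2 HDmax      0.245  3.05  6.09      32
#> 3 HDup      -0.166  2.71  5.42      32

st <- fit_stride_time_model(rec)
estimated_marginal_means(st, "speed")
#>   level   emm
#> 1 fast   747.
#> 2 slow   788.
pairwise_direction_comparisons(st)[, c("level_1", "level_2", "p_adjusted")]
#>   level_1  level_2 p_adjusted
#> 1 straight left      3.16e-18
#> 2 straight right     1.77e-16
#> 3 left     right     1   e+ 0
```

Stride time separates the subjective speed categories (747 vs 788 ms) and
differs between straight line and lunge but not between reins — the
pattern that justifies using stride time as a speed proxy and averaging
the reins. `run_pipeline(study_config(...))` drives the whole chain
(simulate → process → normalize → analyze → report) with CSV artifacts,
and `inst/scripts/lungesym` wraps it for the shell.

## Scientific scope

The methods vignette (`vignettes/lungesym-methods.Rmd`) documents the
signal model, every tunable parameter with units and defaults, the
numerical choices (filter cutoffs, integrator correction, segmentation
tie-breaks), what the synthetic generator does and does not emulate, and
the package's limitations. The package does not diagnose lameness, grade
it visually, or reproduce any specific clinical dataset.
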