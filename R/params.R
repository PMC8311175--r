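#' Parameters of a synthetic trot signal
#'
#' Ground-truth description of one horse's trot used by
#' [simulate_landmark_signal()] and [simulate_trial()]. Midline landmarks
#' (poll, withers, sacrum) oscillate twice per stride; each tuber coxae
#' oscillates with a dominant once-per-stride hike component. Left/right
#' asymmetries are injected exactly at the displacement extrema, so every
#' downstream index has a known true value.
#'
#' The upward-amplitude asymmetry of a midline landmark is not a free
#' parameter: with upward amplitude defined as a maximum minus its
#' immediately preceding minimum, the injected up-difference is structurally
#' `asym_max - asym_min` (the same coupling holds for the real indices).
#'
#' @param stride_time Nominal stride duration \[s\].
#' @param sample_rate Sampling rate \[Hz\]; the sensor contract is 100 Hz.
#' @param duration Record length \[s\]; must cover at least 4 strides.
#' @param amplitude Named vector of vertical oscillation half-amplitudes
#'   \[mm\] for `poll`, `withers`, `sacrum`.
#' @param asym_min,asym_max Named vectors (same names as `amplitude`) of
#'   injected left-minus-right differences \[mm\] in the per-step displacement
#'   minima and maxima.
#' @param tc_up Baseline tuber coxae upward amplitude during the
#'   contralateral hind stance \[mm\].
#' @param tc_rom Baseline tuber coxae total vertical range of motion \[mm\];
#'   must be at least `tc_up + |hike_diff|/2 + |rom_diff|/2`.
#' @param hike_diff Injected hip hike difference (left TC minus right TC
#'   contralateral-stance upward amplitude) \[mm\].
#' @param rom_diff Injected range-of-motion difference (left minus right TC)
#'   \[mm\].
#' @param noise_sd Displacement-referred sensor noise \[mm\]: RMS of a
#'   band-limited (20 Hz) noise floor added to the vertical displacement,
#'   injected into the acceleration channel as its exact second difference.
#' @param stride_time_jitter Fractional stride-to-stride duration jitter (default 0.03,
#'   matching the low stride-time variability of steady-state trot)
#'   (uniform on +/- this fraction).
#'
#' @return An object of class `trot_params` (a validated list).
#' @export
#' @examples
#' trot_params(asym_min = c(poll = 6, withers = 0, sacrum = 4))
trot_params <- function(stride_time = 0.75,
                        sample_rate = 100,
                        duration = 25,
                        amplitude = c(poll = 40, withers = 25, sacrum = 35),
                        asym_min = c(poll = 0, withers = 0, sacrum = 0),
                        asym_max = c(poll = 0, withers = 0, sacrum = 0),
                        tc_up = 20,
                        tc_rom = 35,
                        hike_diff = 0,
                        rom_diff = 0,
                        noise_sd = 0,
                        stride_time_jitter = 0.03) {
  fill_midline <- function(x, what) {
    if (is.null(names(x)) && length(x) == 1) {
      x <- setNames(rep(x, 3), MIDLINE_LANDMARKS)
    }
    missing <- setdiff(MIDLINE_LANDMARKS, names(x))
    x[missing] <- 0
    x[MIDLINE_LANDMARKS]
  }
  amplitude <- fill_midline(amplitude)
  asym_min <- fill_midline(asym_min)
  asym_max <- fill_midline(asym_max)
  if (stride_time <= 0) abort("`stride_time` must be > 0.", class = "lungesym_error_params")
  if (sample_rate <= 0) abort("`sample_rate` must be > 0.", class = "lungesym_error_params")
  if (any(amplitude < 0) || tc_up < 0 || tc_rom < 0) {
    abort("Amplitudes must be >= 0.", class = "lungesym_error_params")
  }
  if (duration < 4 * stride_time) {
    abort("`duration` must cover at least 4 strides.", class = "lungesym_error_params")
  }
  if (tc_rom < tc_up + abs(hike_diff) / 2 + abs(rom_diff) / 2) {
    abort("`tc_rom` too small for the requested `tc_up`/`hike_diff`/`rom_diff`.",
      class = "lungesym_error_params"
    )
  }
  if (noise_sd < 0 || stride_time_jitter < 0 || stride_time_jitter >= 0.5) {
    abort("`noise_sd` must be >= 0 and `stride_time_jitter` in [0, 0.5).",
      class = "lungesym_error_params"
    )
  }
  structure(
    list(
      stride_time = stride_time, sample_rate = sample_rate, duration = duration,
      amplitude = amplitude, asym_min = asym_min, asym_max = asym_max,
      asym_up = asym_max - asym_min,
      tc_up = tc_up, tc_rom = tc_rom, hike_diff = hike_diff, rom_diff = rom_diff,
      noise_sd = noise_sd, stride_time_jitter = stride_time_jitter
    ),
    class = "trot_params"
  )
}

#' Parameters of lunging on a circle
#'
#' Describes one lunging condition: forward speed, circle radius and the
#' direction of travel (the "rein"). The body-lean angle follows from the
#' centripetal force balance `F = m v^2 / r`; `lean_gain` maps that lean
#' angle linearly to additional movement asymmetry directed toward the
#' inside of the circle (the functional form of the lean-to-asymmetry map is
#' a modelling choice; only its mirror symmetry between reins matters
#' downstream).
#'
#' @param speed Forward speed \[m/s\].
#' @param radius Circle radius \[m\]; default 7.5 m (a 15 m lunging circle).
#' @param direction `"left"` or `"right"` rein.
#' @param lean_gain Added asymmetry per degree of body lean \[mm/deg\].
#' @param mass Horse mass \[kg\] (carried for completeness; the lean angle
#'   is mass-independent).
#'
#' @return An object of class `circle_params`.
#' @export
#' @examples
#' circle_params(speed = 3, direction = "left")
circle_params <- function(speed, radius = 7.5, direction = c("left", "right"),
                          lean_gain = 0.8, mass = 500) {
  direction <- match.arg(direction)
  if (radius <= 0) abort("`radius` must be > 0.", class = "lungesym_error_params")
  if (speed < 0) abort("`speed` must be >= 0.", class = "lungesym_error_params")
  if (mass <= 0) abort("`mass` must be > 0.", class = "lungesym_error_params")
  structure(
    list(speed = speed, radius = radius, direction = direction,
         lean_gain = lean_gain, mass = mass),
    class = "circle_params"
  )
}

#' Body lean angle on a circle
#'
#' The inward trunk lean a horse adopts on a circle, derived from balancing
#' gravity against the centripetal force `m v^2 / r`:
#' `atan(v^2 / (g r))`, with `g = 9.81 m/s^2`. Strictly increasing in speed
#' and decreasing in radius.
#'
#' @param speed Forward speed \[m/s\] (vectorized).
#' @param radius Circle radius \[m\] (vectorized).
#' @return Lean angle in degrees.
#' @export
#' @examples
#' body_lean_angle(3, 7.5)
body_lean_angle <- function(speed, radius) {
  if (any(radius <= 0)) abort("`radius` must be > 0.", class = "lungesym_error_params")
  if (any(speed < 0)) abort("`speed` must be >= 0.", class = "lungesym_error_params")
  atan(speed^2 / (GRAVITY * radius)) * 180 / pi
}

#' Design and effect sizes of a simulated lunging study
#'
#' Generative assumptions for [simulate_study()]: per-parameter baselines,
#' a horse-level random intercept, additive surface and speed shifts, a
#' mirror-symmetric circle-induced lean term on the lunge, and residual
#' condition-level noise. Defaults emulate the published study design:
#' 27 horses, up to 12 assessments each (2 surfaces x 2 speeds x 3
#' directions), baselines at the reported straight-line means of the 11
#' parameters, and stride times shaped like the reported estimated marginal
#' means (grand mean 772 ms; fast/slow 753/791 ms; hard/soft 765/779 ms;
#' straight/left/right 747/786/783 ms).
#'
#' @param n_horses Number of horses (>= 2).
#' @param baseline Named numeric vector of per-parameter baseline
#'   asymmetries \[mm\] (defaults to the published straight-line means).
#' @param horse_sd SD of the horse random intercept \[mm\].
#' @param surface_effect Hard-minus-soft shift \[mm\].
#' @param speed_effect Fast-minus-slow shift \[mm\] (direction-independent;
#'   the speed sensitivity of individual reins arises from the lean term).
#' @param residual_sd Condition-level residual SD \[mm\].
#' @param lean_gain Added asymmetry per degree of body lean \[mm/deg\];
#'   set 0 to switch the circle term off.
#' @param radius Lunging circle radius \[m\].
#' @param speed_mps Named vector mapping the speed categories to forward
#'   speeds \[m/s\] used for the lean term.
#' @param conditions Data frame with columns `surface`, `speed`, `direction`
#'   defining the assessed conditions; defaults to the full 12-condition grid.
#' @param stride_time_base Grand-mean stride time \[ms\].
#' @param stride_time_speed Fast-minus-slow stride-time shift \[ms\].
#' @param stride_time_surface Hard-minus-soft stride-time shift \[ms\].
#' @param stride_time_direction Named additive stride-time shifts \[ms\] for
#'   `straight`, `left`, `right`.
#' @param stride_time_horse_sd,stride_time_sd Horse-intercept and residual
#'   SDs for stride time \[ms\].
#'
#' @return An object of class `study_effects`.
#' @export
#' @examples
#' study_effects(n_horses = 8, surface_effect = 2)
study_effects <- function(n_horses = 27,
                          baseline = c(
                            HDmin = 4.23, HDmax = -3.67, HDup = -8.13,
                            WDmin = 1.36, WDmax = -1.38, WDup = -2.46,
                            PDmin = 4.05, PDmax = 0.29, PDup = -3.81,
                            HHD = 4.13, RD = 3.62
                          ),
                          horse_sd = 6,
                          surface_effect = 2,
                          speed_effect = 0,
                          residual_sd = 2.5,
                          lean_gain = 0.8,
                          radius = 7.5,
                          speed_mps = c(slow = 3, fast = 4),
                          conditions = NULL,
                          stride_time_base = 772,
                          stride_time_speed = -38,
                          stride_time_surface = -14,
                          stride_time_direction = c(straight = -25, left = 14, right = 11),
                          stride_time_horse_sd = 25,
                          stride_time_sd = 15) {
  if (n_horses < 2) abort("`n_horses` must be >= 2.", class = "lungesym_error_params")
  if (horse_sd < 0 || residual_sd < 0 || stride_time_horse_sd < 0 || stride_time_sd < 0) {
    abort("Standard deviations must be >= 0.", class = "lungesym_error_params")
  }
  if (is.null(conditions)) {
    conditions <- tidyr::expand_grid(
      surface = SURFACES, speed = SPEEDS, direction = RAW_DIRECTIONS
    )
  }
  conditions <- as_tibble(conditions)
  if (nrow(conditions) == 0) abort("`conditions` must be non-empty.", class = "lungesym_error_params")
  stopifnot(all(c("surface", "speed", "direction") %in% names(conditions)))
  bad <- !(conditions$surface %in% SURFACES) | !(conditions$speed %in% SPEEDS) |
    !(conditions$direction %in% RAW_DIRECTIONS)
  if (any(bad)) abort("Invalid level in `conditions`.", class = "lungesym_error_params")
  miss <- setdiff(asym_parameters(), names(baseline))
  if (length(miss) > 0) {
    abort(paste0("`baseline` missing parameters: ", paste(miss, collapse = ", ")),
      class = "lungesym_error_params"
    )
  }
  structure(
    list(
      n_horses = n_horses, baseline = baseline[asym_parameters()],
      horse_sd = horse_sd, surface_effect = surface_effect,
      speed_effect = speed_effect, residual_sd = residual_sd,
      lean_gain = lean_gain, radius = radius, speed_mps = speed_mps,
      conditions = conditions,
      stride_time_base = stride_time_base,
      stride_time_speed = stride_time_speed,
      stride_time_surface = stride_time_surface,
      stride_time_direction = stride_time_direction,
      stride_time_horse_sd = stride_time_horse_sd,
      stride_time_sd = stride_time_sd
    ),
    class = "study_effects"
  )
}
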