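# Synthetic trot signal generation.
#
# Vertical displacement of each landmark is a two-harmonic trigonometric
# waveform per stride, z(theta) = a0 + a1 cos(theta) + b1 sin(theta)
# - A2 cos(2 theta) with theta the stride phase: the 2/stride component is
# the dominant trot oscillation and the 1/stride component carries the
# left/right asymmetry. The four coefficients are solved by Newton
# iteration so that the waveform's four extrema per stride equal the
# prescribed per-step minima/maxima EXACTLY; the envelope theorem makes
# the Jacobian the plain design matrix at the current extremum phases.
# Being band-limited to twice the stride frequency, the waveform neither
# aliases when sampled nor distorts under the processing filters, and its
# second derivative (the accelerometer channel) is available in closed
# form.

# Fixed sensor mounting angles [deg]; a known, non-trivial rotation shared
# by all synthetic traces.
SENSOR_EULER <- c(roll = 3, pitch = -5, yaw = 15)

# Stride schedule: start times and durations, drawn once per trial seed so
# all landmarks of a trial share the same strides.
sim_schedule <- function(params, seed) {
  n_nominal <- ceiling(params$duration / params$stride_time) + 2
  jit <- withr::with_seed(
    child_seed(seed, 0),
    runif(n_nominal, -params$stride_time_jitter, params$stride_time_jitter)
  )
  durations <- params$stride_time * (1 + jit)
  starts <- cumsum(c(0, durations))[seq_len(n_nominal)]
  tibble(start = starts, duration = durations, end = starts + durations)
}

# Prescribed extremum values [mm] per stride, in cyclic order
# (min ~phase 0, max ~phase 1/4, min ~phase 1/2, max ~phase 3/4).
landmark_extrema <- function(params, landmark) {
  if (landmark %in% MIDLINE_LANDMARKS) {
    A <- params$amplitude[[landmark]]
    dmin <- params$asym_min[[landmark]]
    dmax <- params$asym_max[[landmark]]
    c(-A + dmin / 2, A + dmax / 2, -A - dmin / 2, A - dmax / 2)
  } else if (landmark == "left_tuber_coxae") {
    r <- params$tc_rom + params$rom_diff / 2
    u <- params$tc_up + params$hike_diff / 2
    c(-r / 2, -r / 2 + u, -r / 2, r / 2)
  } else if (landmark == "right_tuber_coxae") {
    r <- params$tc_rom - params$rom_diff / 2
    u <- params$tc_up - params$hike_diff / 2
    c(-r / 2, r / 2, -r / 2, -r / 2 + u)
  } else {
    abort(
      paste0(
        "Unknown landmark '", landmark, "'. Valid landmarks: ",
        paste(LANDMARKS, collapse = ", "), "."
      ),
      class = "lungesym_error_landmark"
    )
  }
}

# Extremum phases of z(theta) = a0 + a1 cos + b1 sin - A2 cos 2theta,
# assigned to the four nominal quarter phases.
trig_extrema <- function(p) {
  # grid extends past 2*pi so roots straddling the phase wrap are caught
  grid <- seq(0, 2 * pi + 0.05, length.out = 750)
  zp <- function(th) -p[2] * sin(th) + p[3] * cos(th) + 2 * p[4] * sin(2 * th)
  v <- zp(grid)
  sgn <- which(v[-1] * v[-length(v)] <= 0 & abs(v[-1] - v[-length(v)]) > 0)
  roots <- vapply(sgn, function(i) {
    stats::uniroot(zp, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  roots <- sort(roots %% (2 * pi))
  if (length(roots) > 1) {
    cyc_dup <- c(FALSE, diff(roots) < 1e-6)
    if ((roots[length(roots)] - roots[1]) > 2 * pi - 1e-6) cyc_dup[length(roots)] <- TRUE
    roots <- roots[!cyc_dup]
  }
  if (length(roots) < 4) return(NULL)
  nominal <- c(0, pi / 2, pi, 3 * pi / 2)
  th <- vapply(nominal, function(t0) {
    d <- abs((roots - t0 + pi) %% (2 * pi) - pi)
    roots[which.min(d)]
  }, numeric(1))
  if (anyDuplicated(round(th, 8)) > 0) return(NULL)
  th
}

# Solve (a0, a1, b1, A2) so the waveform's four extrema equal `targets`.
solve_trig_coefs <- function(targets) {
  v <- targets
  p <- c(
    (v[1] + v[2] + v[3] + v[4]) / 4,
    (v[1] - v[3]) / 2,
    (v[2] - v[4]) / 2,
    (v[2] + v[4] - v[1] - v[3]) / 4
  )
  zval <- function(p, th) p[1] + p[2] * cos(th) + p[3] * sin(th) - p[4] * cos(2 * th)
  for (it in 1:30) {
    th <- trig_extrema(p)
    if (is.null(th)) {
      abort(
        "Injected asymmetries too extreme for a two-harmonic stride waveform.",
        class = "lungesym_error_params"
      )
    }
    w <- zval(p, th)
    if (max(abs(w - v)) < 1e-10) break
    J <- cbind(1, cos(th), sin(th), -cos(2 * th))
    p <- p + solve(J, v - w)
  }
  list(coefs = p, phases = th)
}

# Evaluate displacement [mm] and its second derivative [mm/s^2] at times t
# given the stride schedule.
eval_trig <- function(coefs, sched, t) {
  k <- findInterval(t, sched$start)
  k[k < 1] <- 1
  th <- 2 * pi * (t - sched$start[k]) / sched$duration[k]
  om <- 2 * pi / sched$duration[k]
  p <- coefs
  list(
    disp = p[1] + p[2] * cos(th) + p[3] * sin(th) - p[4] * cos(2 * th),
    acc = om^2 * (-p[2] * cos(th) - p[3] * sin(th) + 4 * p[4] * cos(2 * th))
  )
}

#' Simulate one landmark's trot sensor trace
#'
#' Generates the vertical trot motion of a single landmark together with the
#' tri-axial accelerometer trace a body-mounted sensor would record: the
#' analytic second derivative of the displacement (plus gravity), expressed
#' in a sensor frame tilted by a fixed known rotation, with optional white
#' noise. Midline landmarks oscillate twice per stride with per-step extrema
#' offset by the injected asymmetries; each tuber coxae carries a dominant
#' once-per-stride hike component phase-locked to the contralateral hind
#' stance. The first half of every stride is labelled the left step (left
#' fore / right hind diagonal stance).
#'
#' All landmarks simulated from the same `seed` share one stride schedule,
#' so single-landmark simulations compose into a coherent trial.
#'
#' @param params A [trot_params()] object.
#' @param landmark One of `"poll"`, `"withers"`, `"sacrum"`,
#'   `"left_tuber_coxae"`, `"right_tuber_coxae"`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#'
#' @return An object of class `landmark_sim`: a list with
#'   * `trace`: tibble `t, ax, ay, az, roll, pitch, yaw` (s, m/s^2, deg)
#'     with attributes `landmark` and `sample_rate`;
#'   * `truth`: ground-truth sidecar with the noise-free displacement
#'     \[mm\], per-sample step-side labels, stride boundary times, and the
#'     generating parameters.
#' @export
#' @examples
#' sim <- simulate_landmark_signal(trot_params(duration = 5), "sacrum", seed = 1)
#' head(sim$trace)
simulate_landmark_signal <- function(params, landmark, seed = 1) {
  stopifnot(inherits(params, "trot_params"))
  targets <- landmark_extrema(params, landmark) # validates landmark
  sol <- solve_trig_coefs(targets)
  sched <- sim_schedule(params, seed)

  fs <- params$sample_rate
  t <- seq(0, params$duration - 1 / fs, by = 1 / fs)
  ev <- eval_trig(sol$coefs, sched, t)

  # step side: first half of each stride is the left (LF/RH diagonal) step
  k <- findInterval(t, sched$start)
  phase <- (t - sched$start[k]) / sched$duration[k]
  step_side <- ifelse(phase < 0.5, "left", "right")

  # sensor-frame specific force for constant mounting rotation
  ang <- SENSOR_EULER * pi / 180
  sp <- sin(ang[["pitch"]]); cp <- cos(ang[["pitch"]])
  sr <- sin(ang[["roll"]]); cr <- cos(ang[["roll"]])
  fz <- ev$acc / 1000 + GRAVITY # world z specific force [m/s^2]
  acc <- cbind(ax = fz * sp, ay = fz * cp * sr, az = fz * cp * cr)

  if (params$noise_sd > 0) {
    # displacement-referred sensor noise: white within the sensor band
    # (~20 Hz), scaled to noise_sd [mm] RMS, injected into the
    # acceleration channel as its exact second difference so that double
    # integration reproduces it
    nse <- withr::with_seed(
      child_seed(seed, match(landmark, LANDMARKS)),
      rnorm(length(t) + 2, sd = 1)
    )
    bf <- signal::butter(2, 20 / (fs / 2), type = "low")
    nse <- as.numeric(signal::filtfilt(bf, nse))
    nse <- nse / sd(nse) * params$noise_sd / 1000 # metres
    acc_noise <- diff(diff(nse)) * fs^2
    acc <- acc + acc_noise * cbind(
      rep(sin(ang[["pitch"]]), length(t)),
      cos(ang[["pitch"]]) * sin(ang[["roll"]]),
      cos(ang[["pitch"]]) * cos(ang[["roll"]])
    )
  }

  trace <- tibble(
    t = t, ax = acc[, "ax"], ay = acc[, "ay"], az = acc[, "az"],
    roll = SENSOR_EULER[["roll"]], pitch = SENSOR_EULER[["pitch"]],
    yaw = SENSOR_EULER[["yaw"]]
  )
  attr(trace, "landmark") <- landmark
  attr(trace, "sample_rate") <- fs

  full <- sched$end <= params$duration + 1e-9
  structure(
    list(
      trace = trace,
      truth = list(
        displacement = tibble(t = t, disp_mm = ev$disp),
        step_side = step_side,
        strides = sched[full, ],
        params = params,
        landmark = landmark,
        seed = seed
      )
    ),
    class = "landmark_sim"
  )
}

#' True index values implied by a set of trot parameters
#'
#' The noise-free values of the eleven asymmetry indices that a perfect
#' kinematic analysis would extract from signals generated with `params`
#' (optionally shifted by a circle modulation).
#'
#' @param params A [trot_params()] object.
#' @return One-row tibble with the 11 parameter columns \[mm\].
#' @export
true_indices <- function(params) {
  stopifnot(inherits(params, "trot_params"))
  tibble(
    HDmin = params$asym_min[["poll"]], HDmax = params$asym_max[["poll"]],
    HDup = params$asym_up[["poll"]],
    WDmin = params$asym_min[["withers"]], WDmax = params$asym_max[["withers"]],
    WDup = params$asym_up[["withers"]],
    PDmin = params$asym_min[["sacrum"]], PDmax = params$asym_max[["sacrum"]],
    PDup = params$asym_up[["sacrum"]],
    HHD = params$hike_diff, RD = params$rom_diff
  )
}

# Shift all injected left-minus-right asymmetries by delta [mm]. The tuber
# coxae range of motion is widened if needed so the shifted hike/range
# asymmetries remain geometrically representable.
shift_asymmetry <- function(params, delta) {
  hike <- params$hike_diff + delta
  rom <- params$rom_diff + delta
  trot_params(
    stride_time = params$stride_time, sample_rate = params$sample_rate,
    duration = params$duration, amplitude = params$amplitude,
    asym_min = params$asym_min + delta, asym_max = params$asym_max + delta,
    tc_up = params$tc_up,
    tc_rom = max(params$tc_rom,
      params$tc_up + abs(hike) / 2 + abs(rom) / 2 + 5),
    hike_diff = hike, rom_diff = rom,
    noise_sd = params$noise_sd, stride_time_jitter = params$stride_time_jitter
  )
}

#' Add circle-induced asymmetry to a simulated landmark signal
#'
#' Regenerates the landmark signal with every left-minus-right asymmetry
#' (min, max, hike, range-of-motion differences) shifted by
#' `lean_gain * body_lean_angle(speed, radius)` millimetres toward the
#' inside of the circle: positive (leftward) on the left rein, negative on
#' the right rein. Left- and right-rein modulations at equal speed are exact
#' mirror images, which is the mechanism by which circle-induced asymmetry
#' cancels in average-rein measurements.
#'
#' @param sim A `landmark_sim` from [simulate_landmark_signal()].
#' @param circle A [circle_params()] object.
#' @return A modified `landmark_sim`; `sim$truth$circle` records the
#'   modulation. At `speed = 0` the signal is unchanged.
#' @export
#' @examples
#' sim <- simulate_landmark_signal(trot_params(duration = 5), "poll", seed = 1)
#' lunged <- apply_circle_modulation(sim, circle_params(speed = 3, direction = "left"))
apply_circle_modulation <- function(sim, circle) {
  stopifnot(inherits(sim, "landmark_sim"), inherits(circle, "circle_params"))
  delta <- circle$lean_gain * body_lean_angle(circle$speed, circle$radius) *
    if (circle$direction == "left") 1 else -1
  out <- simulate_landmark_signal(
    shift_asymmetry(sim$truth$params, delta), sim$truth$landmark, sim$truth$seed
  )
  out$truth$circle <- circle
  out$truth$lean_delta_mm <- delta
  out
}

#' Simulate a full five-landmark trial
#'
#' Runs [simulate_landmark_signal()] for all five landmarks under one stride
#' schedule, optionally applying a circle modulation (lunging), and attaches
#' the true index values for parameter-recovery checks.
#'
#' @param params A [trot_params()] object.
#' @param seed Integer seed.
#' @param circle Optional [circle_params()]; `NULL` means straight-line trot.
#' @return An object of class `gait_trial`: list with `landmarks` (named list
#'   of `landmark_sim`), `truth_indices` (one-row tibble), `params`, `seed`,
#'   `circle`.
#' @export
#' @examples
#' trial <- simulate_trial(trot_params(duration = 6), seed = 2)
#' trial$truth_indices
simulate_trial <- function(params, seed = 1, circle = NULL) {
  stopifnot(inherits(params, "trot_params"))
  sims <- lapply(LANDMARKS, function(lm) {
    s <- simulate_landmark_signal(params, lm, seed)
    if (!is.null(circle)) s <- apply_circle_modulation(s, circle)
    s
  })
  names(sims) <- LANDMARKS
  eff_params <- sims[[1]]$truth$params
  structure(
    list(
      landmarks = sims,
      truth_indices = true_indices(eff_params),
      params = params, seed = seed, circle = circle
    ),
    class = "gait_trial"
  )
}
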