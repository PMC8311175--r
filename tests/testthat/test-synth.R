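test_that("body lean angle follows the centripetal force balance", {
  expect_equal(body_lean_angle(0, 7.5), 0)
  expect_equal(body_lean_angle(sqrt(9.81 * 7.5), 7.5), 45)
  expect_equal(body_lean_angle(3, 7.5), 6.9738, tolerance = 1e-4)
  expect_error(body_lean_angle(3, 0), class = "lungesym_error_params")
  expect_error(body_lean_angle(-1, 5), class = "lungesym_error_params")
})

test_that("body lean angle is monotone in speed and radius", {
  speeds <- seq(0.5, 6, by = 0.5)
  radii <- seq(3, 12, by = 1)
  for (r in radii) {
    expect_true(all(diff(body_lean_angle(speeds, r)) > 0))
  }
  for (v in speeds) {
    expect_true(all(diff(body_lean_angle(v, radii)) < 0))
  }
})

test_that("trot parameter validation rejects impossible configurations", {
  expect_error(trot_params(stride_time = 0), class = "lungesym_error_params")
  expect_error(trot_params(duration = 1), class = "lungesym_error_params")
  expect_error(trot_params(tc_up = 30, tc_rom = 20), class = "lungesym_error_params")
  expect_error(
    simulate_landmark_signal(trot_params(), "nose"),
    "poll.*withers.*sacrum",
    class = "lungesym_error_landmark"
  )
})

test_that("simulated waveform extrema carry the injected asymmetries exactly", {
  tp <- quick_params(duration = 15, stride_time_jitter = 0)
  for (lm in c("poll", "sacrum")) {
    sim <- simulate_landmark_signal(tp, lm, seed = 3)
    d <- sim$truth$displacement$disp_mm
    side <- sim$truth$step_side
    strides <- sim$truth$strides
    # per-step minima/maxima from the noise-free truth signal
    fs <- 100
    mins <- c(); maxs <- c(); msides <- c(); xsides <- c()
    for (k in 2:(nrow(strides) - 1)) {
      i0 <- round(strides$start[k] * fs) + 1
      i1 <- round(strides$end[k] * fs)
      for (half in 0:1) {
        w <- seq(i0 + half * (i1 - i0 + 1) %/% 2, i0 + (half + 1) * (i1 - i0 + 1) %/% 2 - 1)
        mx <- w[which.max(d[w])]
        maxs <- c(maxs, d[mx]); xsides <- c(xsides, side[mx])
      }
    }
    dmax <- median(maxs[xsides == "left"]) - median(maxs[xsides == "right"])
    expect_equal(dmax, unname(tp$asym_max[lm]), tolerance = 1e-3)
  }
})

test_that("stride count matches duration / stride_time", {
  tp <- trot_params(duration = 15, stride_time = 0.75, stride_time_jitter = 0)
  sim <- simulate_landmark_signal(tp, "sacrum", seed = 1)
  expect_equal(nrow(sim$truth$strides), 20)
})

test_that("a fixed seed gives bit-identical output and shares one stride schedule", {
  tp <- quick_params(noise_sd = 2, duration = 8)
  a <- simulate_landmark_signal(tp, "poll", seed = 9)
  b <- simulate_landmark_signal(tp, "poll", seed = 9)
  expect_identical(a$trace, b$trace)
  c1 <- simulate_landmark_signal(tp, "withers", seed = 9)
  expect_identical(a$truth$strides, c1$truth$strides)
  d1 <- simulate_landmark_signal(tp, "poll", seed = 10)
  expect_false(identical(a$trace, d1$trace))
})

test_that("circle modulation is a mirror between reins and vanishes at zero speed", {
  tp <- quick_params(duration = 8)
  sim <- simulate_landmark_signal(tp, "poll", seed = 2)
  still <- apply_circle_modulation(sim, circle_params(speed = 0, direction = "left"))
  expect_equal(still$trace, sim$trace)

  left <- apply_circle_modulation(sim, circle_params(speed = 3, direction = "left", lean_gain = 1))
  right <- apply_circle_modulation(sim, circle_params(speed = 3, direction = "right", lean_gain = 1))
  expect_equal(left$truth$lean_delta_mm + right$truth$lean_delta_mm, 0)
  expect_equal(left$truth$lean_delta_mm, body_lean_angle(3, 7.5), tolerance = 1e-10)
  # truth indices shift by +/- delta
  ti_l <- true_indices(left$truth$params)
  ti_r <- true_indices(right$truth$params)
  base <- true_indices(tp)
  expect_equal(ti_l$HDmin - base$HDmin, left$truth$lean_delta_mm)
  expect_equal((unlist(ti_l) + unlist(ti_r)) / 2, unlist(base), tolerance = 1e-10)
})

test_that("simulate_study reproduces its generative model in degenerate limits", {
  eff0 <- study_effects(
    n_horses = 3, horse_sd = 0, surface_effect = 0, speed_effect = 0,
    residual_sd = 0, lean_gain = 0, stride_time_horse_sd = 0, stride_time_sd = 0
  )
  rec <- simulate_study(eff0, seed = 1)
  for (p in asym_parameters()) {
    expect_equal(rec[[p]], rep(eff0$baseline[[p]], nrow(rec)))
  }

  eff2 <- study_effects(
    n_horses = 4, horse_sd = 0, surface_effect = 2, speed_effect = 0,
    residual_sd = 0, lean_gain = 0
  )
  rec2 <- simulate_study(eff2, seed = 1)
  diffs <- tapply(rec2$HDmin, rec2$surface, mean)
  expect_equal(unname(diffs["hard"] - diffs["soft"]), 2)

  expect_identical(simulate_study(eff2, seed = 7), simulate_study(eff2, seed = 7))
})
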