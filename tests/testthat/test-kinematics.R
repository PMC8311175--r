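test_that("frame rotation aligns gravity and removes it", {
  n <- 10
  flat <- data.frame(t = (0:(n - 1)) / 100, ax = 0, ay = 0, az = 9.81,
    roll = 0, pitch = 0, yaw = 0)
  expect_equal(rotate_to_horse_frame(flat), rep(0, n))

  pitched <- data.frame(t = (0:(n - 1)) / 100, ax = 9.81, ay = 0, az = 0,
    roll = 0, pitch = 90, yaw = 33)
  expect_equal(rotate_to_horse_frame(pitched), rep(0, n), tolerance = 1e-12)

  noori <- data.frame(t = 0, ax = 1, ay = 2, az = 3)
  expect_error(rotate_to_horse_frame(noori), "orientation",
    class = "lungesym_error_orientation")
})

test_that("rotation round-trips a known world-frame signal", {
  # oracle: build the sensor-frame acceleration by hand with explicit
  # rotation matrices (pitch positive = nose-up about the left-pointing y)
  rotmat <- function(roll, pitch, yaw) {
    r <- roll * pi / 180; p <- pitch * pi / 180; y <- yaw * pi / 180
    Rx <- matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3)
    Ry <- matrix(c(cos(-p), 0, -sin(-p), 0, 1, 0, sin(-p), 0, cos(-p)), 3)
    Rz <- matrix(c(cos(y), sin(y), 0, -sin(y), cos(y), 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  set.seed(11)
  t <- seq(0, 1, by = 0.01)
  world_z <- 2 * sin(2 * pi * 1.5 * t)
  for (i in 1:5) {
    ang <- runif(3, -40, 40)
    R <- rotmat(ang[1], ang[2], ang[3])
    sensor <- t(t(R) %*% rbind(0, 0, world_z + 9.81))
    trace <- data.frame(t = t, ax = sensor[, 1], ay = sensor[, 2], az = sensor[, 3],
      roll = ang[1], pitch = ang[2], yaw = ang[3])
    expect_equal(rotate_to_horse_frame(trace), world_z, tolerance = 1e-9)
  }
})

test_that("double integration recovers a closed-form sinusoid within 2%", {
  fs <- 100
  T <- 0.75
  A <- 0.030 # 30 mm
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  acc <- -A * (2 * pi / T)^2 * sin(2 * pi * t / T)
  d <- integrate_to_displacement(acc, fs, stride_freq_hint = 1 / T)
  mid <- (5 * fs):((20 - 5) * fs) # trim narrowband filter transients
  amp <- (max(d[mid]) - min(d[mid])) / 2
  expect_lt(abs(amp - A * 1000) / (A * 1000), 0.02)

  expect_equal(integrate_to_displacement(rep(0, 500), fs, 1.3), rep(0, 500))

  bad <- acc
  bad[123] <- NA
  expect_error(integrate_to_displacement(bad, fs, 1 / T), "123",
    class = "lungesym_error_nonfinite")
})

test_that("synthetic amplitude is recovered within 1 mm", {
  tp <- trot_params(duration = 20, amplitude = c(poll = 30, withers = 25, sacrum = 35),
    noise_sd = 0, stride_time_jitter = 0)
  sim <- simulate_landmark_signal(tp, "poll", seed = 4)
  acc <- rotate_to_horse_frame(sim$trace)
  d <- integrate_to_displacement(acc, 100, estimate_stride_frequency(acc, 100))
  mid <- 400:1600
  amp <- (max(d[mid]) - min(d[mid])) / 2
  expect_lt(abs(amp - 30), 1)
})

test_that("stride segmentation finds the right count and times", {
  fs <- 100
  t <- seq(0, 15 - 1 / fs, by = 1 / fs)
  d <- -30 * cos(2 * pi * t / 0.375) # two oscillations per 750 ms stride
  st <- segment_strides(d, fs, min_strides = 10)
  expect_true(nrow(st) %in% c(19, 20))
  expect_true(all(abs(st$stride_time - 750) <= 10))

  expect_error(segment_strides(rep(1, 1000), fs), class = "lungesym_error_segmentation")
  expect_error(segment_strides(d, fs, min_strides = 50),
    class = "lungesym_error_too_few_strides")
})

test_that("segmentation tracks jittered synthetic strides", {
  tp <- trot_params(duration = 20, noise_sd = 1, stride_time_jitter = 0.1)
  sim <- simulate_landmark_signal(tp, "sacrum", seed = 6)
  acc <- rotate_to_horse_frame(sim$trace)
  f <- estimate_stride_frequency(acc, 100)
  d <- integrate_to_displacement(acc, 100, f, tone_bands = FALSE)
  st <- segment_strides(d, 100, min_strides = 10)
  truth <- sim$truth$strides
  expect_lte(abs(nrow(st) - (nrow(truth) - 1)), 2)
  expect_lt(abs(mean(st$stride_time) - 1000 * mean(truth$duration)) /
    (1000 * mean(truth$duration)), 0.01)
})

test_that("step attribution from tuber coxae phase matches ground truth", {
  tp <- quick_params(noise_sd = 1)
  trial <- simulate_trial(tp, seed = 5)
  acc <- lapply(trial$landmarks, function(s) rotate_to_horse_frame(s$trace))
  f <- estimate_stride_frequency(acc$sacrum, 100)
  dl <- integrate_to_displacement(acc$left_tuber_coxae, 100, f)
  dr <- integrate_to_displacement(acc$right_tuber_coxae, 100, f)
  lab <- attribute_steps(dl, dr, 100, f)
  truth <- trial$landmarks[[1]]$truth$step_side
  mid <- 300:1200
  expect_gt(mean(lab[mid] == truth[mid]), 0.9)
})

test_that("indices are invariant to a constant displacement offset", {
  tp <- quick_params()
  trial <- simulate_trial(tp, seed = 8)
  pr <- process_trial(trial, min_strides = 10)
  shifted <- pr$displacement
  shifted$disp_mm <- shifted$disp_mm + 17.3
  f2 <- extract_stride_features(shifted, pr$strides,
    trial$landmarks[[1]]$truth$step_side)
  idx2 <- stride_asymmetry(f2)
  expect_equal(
    as.data.frame(idx2[asym_parameters()]),
    as.data.frame(pr$stride_indices[asym_parameters()]),
    tolerance = 1e-9
  )
})

test_that("clean steady-state data lose no strides to the outlier rule", {
  tp <- quick_params(noise_sd = 0, stride_time_jitter = 0)
  trial <- simulate_trial(tp, seed = 2)
  pr <- process_trial(trial, min_strides = 10)
  expect_equal(pr$log$n_discarded_segmentation, 0)
  expect_equal(pr$log$n_skipped_indices, 0)
})
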