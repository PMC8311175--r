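# Shared fixture builders. Everything is generated in code; seeds are fixed
# so the suite is deterministic.

# a small, fast trot parameter set with known asymmetries
quick_params <- function(noise_sd = 0, duration = 15, ...) {
  trot_params(
    duration = duration, noise_sd = noise_sd,
    asym_min = c(poll = 6, withers = 2, sacrum = 4),
    asym_max = c(poll = -3, withers = 1, sacrum = 2),
    hike_diff = 5, rom_diff = 3,
    ...
  )
}

# a small condition-level study
quick_study <- function(n_horses = 6, seed = 1, ...) {
  simulate_study(study_effects(n_horses = n_horses, ...), seed = seed)
}

# a tidy feature table for one hand-built stride
manual_features <- function(min_l = -10, min_r = -6, max_l = 8, max_r = 8,
                            up_tc_l = 25, up_tc_r = 20, rom_l = 40, rom_r = 40,
                            stride_id = 1L) {
  midline <- tidyr::expand_grid(
    landmark = c("poll", "withers", "sacrum"),
    feature = c("min", "max", "up"),
    side = c("left", "right")
  )
  midline$value_mm <- rep(c(min_l, min_r, max_l, max_r, max_l - min_l, max_r - min_r),
    times = 3
  )
  tc <- tibble::tibble(
    landmark = rep(c("left_tuber_coxae", "right_tuber_coxae"), each = 2),
    feature = rep(c("up_contra", "rom"), 2),
    side = rep(c("left", "right"), each = 2),
    value_mm = c(up_tc_l, rom_l, up_tc_r, rom_r)
  )
  dplyr::bind_rows(midline, tc) |>
    dplyr::mutate(stride_id = stride_id, .before = 1)
}

expect_errclass <- function(expr, class) {
  expect_error(expr, class = class)
}
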