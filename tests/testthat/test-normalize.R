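mini_records <- function() {
  rec <- quick_study(n_horses = 4, seed = 3)
  rec
}

test_that("preexisting sign is the sign of the mean straight-line value", {
  base <- quick_study(n_horses = 2, seed = 1)[0, ]
  row <- function(horse, direction, HDmin, surface = "hard", speed = "slow") {
    out <- tibble::as_tibble(as.list(setNames(rep(0, 11), asym_parameters())))
    out$HDmin <- HDmin
    dplyr::bind_cols(tibble::tibble(horse = horse, surface = surface,
      speed = speed, direction = direction), out,
      tibble::tibble(stride_time = 750, n_strides = 30L))
  }
  rec <- dplyr::bind_rows(
    row("h1", "straight", 3, speed = "slow"),
    row("h1", "straight", 5, speed = "fast"),
    row("h2", "straight", 2, speed = "slow"),
    row("h2", "straight", -6, speed = "fast"),
    row("h3", "straight", -0.1)
  )
  s <- suppressWarnings(preexisting_sign(rec)) # other parameters are all-zero here
  hd <- s[s$parameter == "HDmin", ]
  expect_equal(hd$sign[hd$horse == "h1"], 1)
  expect_equal(hd$sign[hd$horse == "h2"], -1) # mean 2 - 6 = -2
  expect_equal(hd$sign[hd$horse == "h3"], -1)
  expect_equal(hd$side[hd$horse == "h2"], "right")

  lunge_only <- row("h9", "left", 4)
  expect_error(preexisting_sign(dplyr::bind_rows(rec, lunge_only)), "h9",
    class = "lungesym_error_no_straight")

  zero <- row("h4", "straight", 0)
  expect_warning(sz <- preexisting_sign(zero), "zero")
  expect_true(all(sz$sign == 1))
})

test_that("sign normalization inverts whole horse-parameter series and is idempotent", {
  rec <- mini_records()
  norm <- normalize_signs(rec)
  # straight-line means all non-negative afterwards
  means <- norm |>
    dplyr::filter(rein == "straight") |>
    dplyr::group_by(horse, parameter) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  expect_true(all(means$m >= -1e-12))

  # inverted values are exactly the negation of the originals
  long0 <- tidyr::pivot_longer(rec, dplyr::all_of(asym_parameters()),
    names_to = "parameter", values_to = "orig")
  joined <- dplyr::inner_join(norm,
    long0[, c("horse", "surface", "speed", "direction", "parameter", "orig")],
    by = c("horse", "surface", "speed", rein = "direction", "parameter"))
  expect_equal(joined$value, ifelse(joined$inverted, -joined$orig, joined$orig))

  # idempotence
  norm2 <- normalize_signs(norm)
  expect_equal(norm2$value, norm$value)
  expect_true(!any(norm2$inverted))
})

test_that("inside/outside labels follow the preexisting side", {
  rec <- mini_records()
  norm <- assign_inside_outside(normalize_signs(rec))
  expect_true(all(norm$direction[norm$rein == "straight"] == "straight"))
  left_rows <- norm[norm$rein == "left", ]
  expect_true(all(left_rows$direction[left_rows$side == "left"] == "inside"))
  expect_true(all(left_rows$direction[left_rows$side == "right"] == "outside"))
  right_rows <- norm[norm$rein == "right", ]
  expect_true(all(right_rows$direction[right_rows$side == "left"] == "outside"))

  stripped <- dplyr::select(normalize_signs(rec), -side)
  expect_error(assign_inside_outside(stripped), class = "lungesym_error_no_side")
})

test_that("average rein rows are means of matched inside/outside pairs only", {
  rec <- mini_records()
  norm <- average_rein(assign_inside_outside(normalize_signs(rec)), quiet = TRUE)
  avg <- norm[norm$direction == "average", ]
  reins <- norm[norm$direction %in% c("inside", "outside"), ]
  check <- reins |>
    dplyr::group_by(horse, surface, speed, parameter) |>
    dplyr::summarise(m = mean(value), n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(n == 2)
  joined <- dplyr::inner_join(avg, check,
    by = c("horse", "surface", "speed", "parameter"))
  expect_equal(nrow(joined), nrow(avg))
  expect_equal(joined$value, joined$m)

  # drop one rein of one condition: its average row disappears
  drop1 <- rec[!(rec$horse == rec$horse[1] & rec$surface == "hard" &
    rec$speed == "slow" & rec$direction == "left"), ]
  norm1 <- suppressMessages(normalize_asymmetry(drop1))
  gone <- norm1[norm1$direction == "average" & norm1$horse == rec$horse[1] &
    norm1$surface == "hard" & norm1$speed == "slow", ]
  expect_equal(nrow(gone), 0)
})

test_that("average rein commutes with sign inversion", {
  rec <- mini_records()
  norm <- assign_inside_outside(normalize_signs(rec))
  flip <- function(df) dplyr::mutate(df, value = ifelse(parameter == "HDmin", -value, value))
  a <- average_rein(flip(norm), quiet = TRUE)
  b <- flip(average_rein(norm, quiet = TRUE))
  key <- c("horse", "surface", "speed", "parameter", "direction")
  a_avg <- dplyr::arrange(a[a$direction == "average", ], !!!rlang::syms(key))
  b_avg <- dplyr::arrange(b[b$direction == "average", ], !!!rlang::syms(key))
  expect_equal(a_avg$value, b_avg$value)
})

test_that("preexisting flags use strict clinical thresholds", {
  rec <- quick_study(n_horses = 2, seed = 2,
    horse_sd = 0, residual_sd = 0, surface_effect = 0, lean_gain = 0,
    baseline = c(HDmin = 7, HDmax = 0, HDup = 0, WDmin = 0, WDmax = 0,
      WDup = 0, PDmin = 3, PDmax = 0, PDup = 0, HHD = 0, RD = 0))
  fl <- flag_preexisting(rec)
  expect_true(all(fl$flag[fl$parameter == "HDmin"]))
  expect_false(any(fl$flag[fl$parameter == "PDmin"])) # exactly 3: strict >
  expect_false(any(fl$flag[fl$parameter %in% c("HDmax", "PDmax", "HHD")]))
})
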