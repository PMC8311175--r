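test_that("descriptives compute mean, mean-abs and side counts", {
  rec <- quick_study(n_horses = 5, seed = 4)
  ds <- describe_asymmetry(rec)
  straight <- rec[rec$direction == "straight", ]
  expect_equal(ds$mean[ds$parameter == "HDmin"], mean(straight$HDmin))
  expect_equal(ds$mean_abs[ds$parameter == "HDmin"], mean(abs(straight$HDmin)))
  expect_equal(ds$n_left + ds$n_right, rep(5, 11))

  hand <- straight[1:2, ]
  hand$HDmin <- c(-3, 3)
  hand$horse <- c("hA", "hB")
  d2 <- describe_asymmetry(hand)
  expect_equal(d2$mean[d2$parameter == "HDmin"], 0)
  expect_equal(d2$mean_abs[d2$parameter == "HDmin"], 3)
  expect_equal(d2$sd[d2$parameter == "HDmin"], sd(c(-3, 3)))

  single <- straight[1, ]
  d1 <- describe_asymmetry(single)
  expect_equal(d1$sd, rep(0, 11))
  expect_equal(d1$n, rep(1L, 11))
})

test_that("intra-horse SD pools deviations with the n-1 denominator", {
  rec <- quick_study(n_horses = 3, seed = 5)
  one <- rec[rec$direction == "straight" & rec$horse == "horse01", ][1:2, ]
  one$HDmin <- c(4, 8)
  one$surface <- c("hard", "soft")
  ih <- intra_horse_sd(one)
  expect_equal(ih$pooled$intra_horse_sd[ih$pooled$parameter == "HDmin"],
    2 * sqrt(2))

  # horses with a single straight condition are excluded
  rec1 <- rec[rec$direction == "straight", ] |>
    dplyr::distinct(horse, .keep_all = TRUE)
  expect_error(intra_horse_sd(rec1), class = "lungesym_error_empty")

  # all conditions identical -> zero
  same <- dplyr::bind_rows(one, one) |>
    dplyr::mutate(HDmin = 5, speed = rep(c("slow", "fast"), each = 2))
  ih0 <- intra_horse_sd(same)
  expect_equal(ih0$pooled$intra_horse_sd[ih0$pooled$parameter == "HDmin"], 0)
})

test_that("limits of agreement match hand computation and flip sign correctly", {
  norm <- normalize_asymmetry(quick_study(n_horses = 5, seed = 6), quiet = TRUE)
  loa <- limits_of_agreement(norm)
  expect_s3_class(loa, "lungesym_loa")
  expect_equal(loa$band, 2 * loa$sd)

  # brute-force oracle on the matched pairs
  pairs <- attr(loa, "pairs")
  for (p in c("HDmin", "RD")) {
    d <- pairs$diff[pairs$parameter == p]
    expect_equal(loa$bias[loa$parameter == p], sum(d) / length(d))
    expect_equal(loa$sd[loa$parameter == p],
      sqrt(sum((d - mean(d))^2) / (length(d) - 1)))
  }

  # negating straight and average flips bias, keeps sd
  flipped <- dplyr::mutate(norm, value = -value)
  loa2 <- limits_of_agreement(flipped)
  expect_equal(loa2$bias, -loa$bias)
  expect_equal(loa2$sd, loa$sd)

  expect_error(limits_of_agreement(norm[norm$direction == "straight", ]),
    class = "lungesym_error_too_few_pairs")
})

test_that("linear trend matches closed-form least squares", {
  expect_equal(linear_trend(0:5, 0:5),
    tibble::tibble(slope = 1, intercept = 0, r2 = 1, n = 6L))
  t2 <- linear_trend(c(0, 1, 2), c(0, 1, 3))
  expect_equal(t2$slope, 1.5)
  expect_equal(t2$intercept, -1 / 6)
  yc <- linear_trend(c(0, 1, 2), c(4, 4, 4))
  expect_equal(yc$slope, 0)
  expect_equal(yc$r2, 0)
  expect_error(linear_trend(rep(2, 5), 1:5), class = "lungesym_error_trend")
  expect_error(linear_trend(1:2, 1:2), class = "lungesym_error_trend")

  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    tf <- linear_trend(x, y)
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(tf$slope, sl, tolerance = 1e-10)
    expect_equal(tf$intercept, mean(y) - sl * mean(x), tolerance = 1e-10)
    expect_equal(tf$r2, stats::cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("straight vs rein trends cover average, inside and outside", {
  norm <- normalize_asymmetry(quick_study(n_horses = 6, seed = 7), quiet = TRUE)
  tr <- straight_vs_rein_trends(norm)
  expect_setequal(unique(tr$comparison), c("average", "inside", "outside"))
  expect_equal(nrow(tr), 33)
  expect_true(all(tr$r2 >= 0 & tr$r2 <= 1))
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})

test_that("bonferroni adjustment is min(1, p*m), monotone and capped", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  expect_error(bonferroni_adjust(1.2, 2), class = "lungesym_error_params")
  expect_error(bonferroni_adjust(0.1, 0), class = "lungesym_error_params")
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroni_adjust(p, 3)) >= 0))
  expect_true(all(bonferroni_adjust(p, 7) >= bonferroni_adjust(p, 2)))
  expect_true(all(bonferroni_adjust(p, 50) <= 1))
})
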