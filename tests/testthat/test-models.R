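test_that("the zero-variance limit reproduces ordinary least squares", {
  eff <- study_effects(n_horses = 4, horse_sd = 0, residual_sd = 0,
    surface_effect = 2, speed_effect = 0, lean_gain = 0)
  rec <- simulate_study(eff, seed = 1)
  d <- rec[rec$direction == "straight", ]
  m <- suppressWarnings(fit_gait_model(d, "HDmin", c("surface", "speed")))
  emm <- estimated_marginal_means(m, "surface")
  expect_equal(emm$emm[emm$level == "hard"] - emm$emm[emm$level == "soft"], 2,
    tolerance = 1e-8)
  # OLS oracle
  ols <- lm(HDmin ~ surface + speed, data = d)
  expect_equal(unname(coef(ols)["surfacesoft"]), -2, tolerance = 1e-8)
  expect_lt(glance(m)$var_horse, 0.1)
})

test_that("a constant response yields p = 1 and equal marginal means", {
  rec <- quick_study(n_horses = 3, seed = 2)
  rec$HDmin <- 5
  m <- fit_gait_model(rec, "HDmin", c("surface", "speed"))
  expect_true(all(m$tests$p_value == 1))
  expect_true(all(m$emm$emm == 5))
})

test_that("balanced-grid marginal means agree with emmeans", {
  rec <- quick_study(n_horses = 8, seed = 3)
  norm <- normalize_asymmetry(rec, quiet = TRUE)
  d <- norm[norm$parameter == "PDmin" & norm$direction %in% c("straight", "average"), ]
  m <- fit_gait_model(d, "value", c("surface", "speed", "direction"))
  em <- suppressMessages(emmeans::emmeans(m$fit, "surface", lmer.df = "asymptotic"))
  em <- as.data.frame(em)
  ours <- estimated_marginal_means(m, "surface")
  expect_equal(ours$emm, em$emmean[match(ours$level, em$surface)],
    tolerance = 1e-6)
})

test_that("marginal means recover effects that raw means miss in unbalanced data", {
  # horses 1-4 are mostly measured on hard, horses 5-8 on soft, and horses
  # differ systematically: raw level means confound horse and surface
  set.seed(4)
  rows <- list()
  for (h in 1:8) {
    int <- ifelse(h <= 4, 10, 0)
    n_hard <- ifelse(h <= 4, 6, 2)
    for (i in 1:8) {
      surf <- ifelse(i <= n_hard, "hard", "soft")
      rows[[length(rows) + 1]] <- data.frame(
        horse = paste0("h", h), surface = surf,
        speed = rep(c("slow", "fast"), 4)[i],
        y = int + 2 * (surf == "hard") + rnorm(1, sd = 0.3)
      )
    }
  }
  d <- do.call(rbind, rows)
  m <- fit_gait_model(d, "y", c("surface", "speed"))
  emm <- estimated_marginal_means(m, "surface")
  model_diff <- emm$emm[emm$level == "hard"] - emm$emm[emm$level == "soft"]
  raw_diff <- mean(d$y[d$surface == "hard"]) - mean(d$y[d$surface == "soft"])
  expect_lt(abs(model_diff - 2), 0.5)
  expect_gt(abs(raw_diff - 2), 2) # confounded raw means are far off
})

test_that("model failure modes are loud", {
  rec <- quick_study(n_horses = 3, seed = 5)
  expect_error(fit_gait_model(rec[rec$horse == "horse01", ], "HDmin", "surface"),
    class = "lungesym_error_model")
  one_level <- rec[rec$surface == "hard", ]
  expect_error(fit_gait_model(one_level, "HDmin", c("surface", "speed")),
    class = "lungesym_error_model")
  m <- fit_gait_model(rec, "HDmin", c("surface", "speed"))
  expect_error(estimated_marginal_means(m, "diet"), class = "lungesym_error_model")
})

test_that("stride-time model shows the expected direction pattern", {
  rec <- simulate_study(study_effects(n_horses = 14), seed = 6)
  m <- fit_stride_time_model(rec)
  expect_true(m$converged)
  p <- m$tests$p_value
  names(p) <- m$tests$factor
  expect_lt(p[["speed"]], 0.05)
  expect_lt(p[["direction"]], 0.05)
  emm_speed <- estimated_marginal_means(m, "speed")
  expect_lt(emm_speed$emm[emm_speed$level == "fast"],
    emm_speed$emm[emm_speed$level == "slow"])

  pw <- pairwise_direction_comparisons(m)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 3))
  sl <- pw[pw$level_1 == "straight" & pw$level_2 == "left", ]
  lr <- pw[pw$level_1 == "left" & pw$level_2 == "right", ]
  expect_lt(sl$p_adjusted, 0.05)
  expect_gt(lr$p_adjusted, 0.05)

  two_dir <- rec[rec$direction != "right", ]
  m2 <- fit_gait_model(two_dir, "stride_time", c("surface", "direction", "speed"))
  expect_error(pairwise_direction_comparisons(m2), class = "lungesym_error_model")
})

test_that("wald tests agree with car::Anova on the same fit", {
  rec <- quick_study(n_horses = 8, seed = 7)
  m <- fit_gait_model(rec, "HDmin", c("surface", "speed", "direction"))
  a <- car::Anova(m$fit, test.statistic = "Chisq")
  # our F with df1=q equals the Wald chi-square / q
  for (f in m$tests$factor) {
    chi <- a[f, "Chisq"]
    q <- m$tests$df1[m$tests$factor == f]
    expect_equal(m$tests$f_stat[m$tests$factor == f], chi / q, tolerance = 1e-6)
  }
})

test_that("tidy, glance and autoplot work on fitted gait models", {
  rec <- quick_study(n_horses = 5, seed = 8)
  m <- fit_gait_model(rec, "WDup", c("surface", "speed"))
  td <- tidy(m)
  expect_setequal(td$factor, c("surface", "speed"))
  expect_true(all(c("p_value", "emm_abs_diff") %in% names(td)))
  gl <- glance(m)
  expect_true(all(c("var_horse", "var_residual", "converged", "singular") %in%
    names(gl)))
  expect_s3_class(autoplot(m), "ggplot")
})
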