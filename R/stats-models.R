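# Random-intercept mixed models, Wald tests, balanced-grid estimated
# marginal means, Bonferroni adjustment.

#' Bonferroni-adjust a p-value
#'
#' `min(1, p * m)`: the unadjusted (Fisher's least significant difference)
#' p-value multiplied by the number of comparisons, capped at 1, so
#' significance can be read against the usual alpha = 0.05.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' bonferroni_adjust(0.01, 3)
bonferroni_adjust <- function(p, m) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must be in [0, 1].", class = "lungesym_error_params")
  }
  if (any(m < 1)) abort("`m` must be >= 1.", class = "lungesym_error_params")
  pmin(1, p * m)
}

# balanced reference grid over the model's fixed factors
balanced_grid <- function(xlevels) {
  do.call(tidyr::expand_grid, lapply(xlevels, identity))
}

#' Fit a random-intercept mixed model for one gait outcome
#'
#' Fits `response ~ fixed effects + (1 | horse)` by restricted maximum
#' likelihood (lme4). Per-factor p-values are Wald F tests of the factor's
#' coefficients against zero, with residual degrees of freedom
#' (observations minus fixed-effect columns); estimated marginal means are
#' model predictions averaged over a balanced grid of the other fixed
#' factors. Non-convergence and singular random-effect fits are flagged,
#' never silent; with `drop_singular_random = TRUE` a singular fit is
#' refitted as a fixed-effects-only linear model.
#'
#' @param data Data frame with columns `horse`, the fixed factors and the
#'   response.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-factor column names.
#' @param reml Use REML (default `TRUE`).
#' @param drop_singular_random Refit without the random term if the random
#'   intercept variance collapses to zero (default `FALSE`).
#' @return Object of class `gait_model`: list with `fit`, `tests`
#'   (per-factor F, df, p), `emm` (per factor x level), `emm_diff`
#'   (absolute difference between the first two levels of each factor),
#'   `varcomp` \[mm^2\], `residuals`, `converged`, `singular`, `n`,
#'   `df_residual`.
#' @export
#' @examples
#' rec <- simulate_study(study_effects(n_horses = 6), seed = 1)
#' norm <- normalize_asymmetry(rec, quiet = TRUE)
#' d <- dplyr::filter(norm, parameter == "PDmin", direction %in% c("inside"))
#' m <- fit_gait_model(d, "value", c("surface", "speed"))
#' tidy(m)
fit_gait_model <- function(data, response, fixed, reml = TRUE,
                           drop_singular_random = FALSE) {
  stopifnot("horse" %in% names(data), response %in% names(data),
    all(fixed %in% names(data)))
  data <- as.data.frame(data)
  if (dplyr::n_distinct(data$horse) < 2) {
    abort("Need at least 2 horses.", class = "lungesym_error_model")
  }
  level_order <- list(
    surface = SURFACES, speed = c("fast", "slow"),
    direction = c("straight", "average", "inside", "outside", "left", "right")
  )
  for (f in fixed) {
    lev <- unique(as.character(data[[f]]))
    if (length(lev) < 2) {
      abort(paste0("Fixed factor '", f, "' has fewer than 2 observed levels."),
        class = "lungesym_error_model"
      )
    }
    ord <- level_order[[f]]
    lev <- if (is.null(ord)) sort(lev) else intersect(ord, lev)
    data[[f]] <- factor(as.character(data[[f]]), levels = lev)
  }
  y <- data[[response]]
  xlev <- lapply(data[fixed], levels)
  names(xlev) <- fixed

  # degenerate constant response: nothing to test
  if (sd(y) < 1e-12) {
    grid <- balanced_grid(xlev)
    emm <- purrr::map2_dfr(fixed, xlev[fixed], function(f, ls) {
      tibble(factor = f, level = ls, emm = y[1])
    })
    return(structure(list(
      fit = NULL,
      tests = tibble(factor = fixed, f_stat = 0, df1 = NA_real_,
        df2 = NA_real_, p_value = 1),
      emm = emm,
      emm_diff = tibble(factor = fixed, diff = 0),
      varcomp = tibble(component = c("horse", "residual"), variance = c(0, 0)),
      residuals = rep(0, nrow(data)),
      converged = TRUE, singular = TRUE, n = nrow(data),
      df_residual = NA_real_, xlevels = xlev, response = response,
      fixed = fixed, data = data
    ), class = "gait_model"))
  }

  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+ (1 | horse)"
  ))
  fit <- lme4::lmer(fml, data = data, REML = reml)
  singular <- lme4::isSingular(fit, tol = 1e-5)
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || length(msgs) == 0

  use_lm <- singular && drop_singular_random
  if (use_lm) {
    fml_lm <- stats::as.formula(paste(response, "~", paste(fixed, collapse = " + ")))
    fit <- lm(fml_lm, data = data)
    converged <- TRUE
  }

  if (inherits(fit, "lmerMod")) {
    X <- lme4::getME(fit, "X")
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- tibble(
      component = c("horse", "residual"),
      variance = c(vc$vcov[vc$grp == "horse"], vc$vcov[vc$grp == "Residual"])
    )
    res <- stats::residuals(fit)
  } else {
    X <- model.matrix(fit)
    beta <- coef(fit)
    V <- vcov(fit)
    s2 <- summary(fit)$sigma^2
    varcomp <- tibble(component = c("horse", "residual"), variance = c(0, s2))
    res <- stats::residuals(fit)
  }
  n <- nrow(X)
  df_resid <- n - ncol(X)
  asg <- attr(X, "assign")
  term_labels <- attr(stats::terms(stats::as.formula(
    paste("~", paste(fixed, collapse = " + "))
  )), "term.labels")

  tests <- purrr::map_dfr(seq_along(term_labels), function(ti) {
    idx <- which(asg == ti)
    b <- beta[idx]
    Vff <- V[idx, idx, drop = FALSE]
    q <- length(idx)
    fstat <- as.numeric(t(b) %*% solve(Vff) %*% b) / q
    tibble(
      factor = term_labels[ti], f_stat = fstat, df1 = q, df2 = df_resid,
      p_value = pf(fstat, q, df_resid, lower.tail = FALSE)
    )
  })

  # balanced-grid EMMs
  grid <- balanced_grid(xlev)
  tt <- stats::delete.response(stats::terms(stats::as.formula(
    paste(response, "~", paste(fixed, collapse = " + "))
  )))
  Xg <- model.matrix(tt, data = grid, xlev = xlev)
  pred <- as.numeric(Xg %*% beta)
  emm <- purrr::map_dfr(fixed, function(f) {
    purrr::map_dfr(xlev[[f]], function(l) {
      tibble(factor = f, level = l, emm = mean(pred[grid[[f]] == l]))
    })
  })
  emm_diff <- emm %>%
    group_by(.data$factor) %>%
    summarise(diff = abs(.data$emm[1] - .data$emm[2]), .groups = "drop")

  structure(list(
    fit = fit, tests = tests, emm = emm, emm_diff = emm_diff,
    varcomp = varcomp, residuals = res, converged = converged,
    singular = singular, n = n, df_residual = df_resid,
    xlevels = xlev, grid = grid, grid_pred = pred, beta = beta, V = V,
    response = response, fixed = fixed, data = data
  ), class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat("<gait_model> ", x$response, " ~ ", paste(x$fixed, collapse = " + "),
    " + (1|horse), n = ", x$n,
    if (x$singular) " [singular random effect]" else "",
    if (!x$converged) " [NOT CONVERGED]" else "", "\n",
    sep = ""
  )
  print(x$tests)
  invisible(x)
}

#' @export
tidy.gait_model <- function(x, ...) {
  x$tests %>%
    left_join(x$emm_diff, by = "factor") %>%
    rename(emm_abs_diff = "diff")
}

#' @export
glance.gait_model <- function(x, ...) {
  tibble(
    n = x$n, df_residual = x$df_residual,
    var_horse = x$varcomp$variance[x$varcomp$component == "horse"],
    var_residual = x$varcomp$variance[x$varcomp$component == "residual"],
    converged = x$converged, singular = x$singular
  )
}

#' @export
autoplot.gait_model <- function(object, bins = 20, ...) {
  ggplot2::ggplot(
    data.frame(residual = as.numeric(object$residuals)),
    ggplot2::aes(x = .data$residual)
  ) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "grey30") +
    ggplot2::labs(
      x = "Model residual [mm]", y = "Count",
      title = paste("Residuals:", object$response)
    )
}

#' Estimated marginal means of a fitted gait model
#'
#' Model predictions per level of one fixed factor, averaged over a
#' balanced grid of the other fixed factors (the classical marginal-means
#' definition), with the absolute difference between levels.
#'
#' @param model A `gait_model`.
#' @param factor Name of a fixed factor in the model.
#' @return Tibble `level`, `emm` \[mm\] with attribute `abs_diff` (absolute
#'   difference between the first two levels).
#' @export
estimated_marginal_means <- function(model, factor) {
  stopifnot(inherits(model, "gait_model"))
  if (!factor %in% model$fixed) {
    abort(paste0("Unknown factor '", factor, "'. Model factors: ",
      paste(model$fixed, collapse = ", ")), class = "lungesym_error_model")
  }
  out <- model$emm %>%
    filter(.data$factor == !!factor) %>%
    select("level", "emm")
  attr(out, "abs_diff") <- abs(out$emm[1] - out$emm[2])
  out
}

#' Bonferroni-corrected pairwise comparisons between factor levels
#'
#' All pairwise contrasts of the balanced-grid estimated marginal means of
#' one factor (by default the three movement directions of the stride-time
#' model), tested with Wald t statistics on residual degrees of freedom and
#' Bonferroni-adjusted by the number of pairs.
#'
#' @param model A `gait_model` whose `factor` has at least 3 levels.
#' @param factor Factor to compare (default `"direction"`).
#' @return Tibble `level_1`, `level_2`, `estimate` \[mm or ms\], `se`,
#'   `t_stat`, `p_value` (raw), `p_adjusted` (Bonferroni, m = number of
#'   pairs).
#' @export
pairwise_direction_comparisons <- function(model, factor = "direction") {
  stopifnot(inherits(model, "gait_model"))
  if (!factor %in% model$fixed) {
    abort(paste0("Unknown factor '", factor, "'."), class = "lungesym_error_model")
  }
  levs <- model$xlevels[[factor]]
  if (length(levs) < 3) {
    abort("Pairwise comparisons need a factor with at least 3 levels.",
      class = "lungesym_error_model"
    )
  }
  if (is.null(model$fit)) {
    abort("Degenerate (constant-response) model; no comparisons.",
      class = "lungesym_error_model"
    )
  }
  # contrast vectors: difference of grid-averaged model-matrix rows
  tt <- stats::delete.response(stats::terms(stats::as.formula(
    paste(model$response, "~", paste(model$fixed, collapse = " + "))
  )))
  Xg <- model.matrix(tt, data = model$grid, xlev = model$xlevels)
  rowmean <- function(l) colMeans(Xg[model$grid[[factor]] == l, , drop = FALSE])
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    cvec <- rowmean(pr[1]) - rowmean(pr[2])
    est <- sum(cvec * model$beta)
    se <- sqrt(as.numeric(t(cvec) %*% model$V %*% cvec))
    tstat <- est / se
    p <- 2 * pt(-abs(tstat), model$df_residual)
    tibble(
      level_1 = pr[1], level_2 = pr[2], estimate = est, se = se,
      t_stat = tstat, p_value = p, p_adjusted = bonferroni_adjust(p, m)
    )
  })
}

#' Fit the 11 per-parameter asymmetry models
#'
#' One random-intercept model per asymmetry parameter over the requested
#' direction subset: for the straight-vs-average analysis use
#' `directions = c("straight", "average")` with
#' `fixed = c("surface", "speed", "direction")`; for per-rein models use
#' `directions = "inside"` (or `"outside"`) with
#' `fixed = c("surface", "speed")`.
#'
#' @param normalized Long normalized tibble.
#' @param directions Direction levels to include.
#' @param fixed Fixed factors.
#' @param parameters Parameters to model.
#' @param reml Use REML.
#' @return Tibble `parameter`, `model` (list of `gait_model`), unnested
#'   tidy test results per factor.
#' @export
#' @examples
#' norm <- normalize_asymmetry(simulate_study(study_effects(n_horses = 6), seed = 1))
#' fits <- fit_asymmetry_models(norm, directions = "inside",
#'                              fixed = c("surface", "speed"))
fit_asymmetry_models <- function(normalized,
                                 directions = c("straight", "average"),
                                 fixed = c("surface", "speed", "direction"),
                                 parameters = asym_parameters(),
                                 reml = TRUE) {
  dat <- normalized %>% filter(.data$direction %in% directions)
  purrr::map_dfr(parameters, function(p) {
    d <- dat %>% filter(.data$parameter == p)
    mod <- fit_gait_model(d, "value", fixed, reml = reml)
    tidy(mod) %>%
      mutate(parameter = p, model = list(mod), .before = 1)
  })
}

#' Fit the stride-time mixed model
#'
#' Stride time as outcome with horse as random factor and surface, speed
#' and movement direction (straight/left/right) as fixed factors - the
#' check that the subjective speed categories separate in stride time and
#' that the reins do not differ.
#'
#' @param records Wide condition table with a `stride_time` column \[ms\].
#' @param reml Use REML.
#' @return A `gait_model` for `stride_time`.
#' @export
#' @examples
#' m <- fit_stride_time_model(simulate_study(study_effects(n_horses = 6), seed = 1))
#' estimated_marginal_means(m, "speed")
fit_stride_time_model <- function(records, reml = TRUE) {
  fit_gait_model(records, "stride_time", c("surface", "direction", "speed"),
    reml = reml
  )
}
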