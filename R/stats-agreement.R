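# Bland-Altman limits of agreement and straight-vs-rein trend fits.

#' Bland-Altman limits of agreement: straight vs average rein
#'
#' Differences `straight - average` are formed between matching assessment
#' conditions (same horse, surface and speed); their mean (bias), SD (n-1)
#' and the 2 x SD band express the limits of agreement, per parameter.
#'
#' @param normalized Long normalized tibble with `average` rows (from
#'   [normalize_asymmetry()]).
#' @param parameters Parameters to assess.
#' @return Object of class `lungesym_loa`: tibble `parameter`, `bias`
#'   \[mm\], `sd` \[mm\], `band` (= 2 sd) \[mm\], `n_pairs`; the matched
#'   pair differences are kept in the `pairs` attribute for plotting.
#' @export
#' @examples
#' norm <- normalize_asymmetry(simulate_study(study_effects(n_horses = 5), seed = 1))
#' limits_of_agreement(norm)
limits_of_agreement <- function(normalized, parameters = asym_parameters()) {
  key <- c("horse", "surface", "speed", "parameter")
  straight <- normalized %>%
    filter(.data$direction == "straight", .data$parameter %in% parameters) %>%
    select(all_of(key), straight = "value")
  avg <- normalized %>%
    filter(.data$direction == "average", .data$parameter %in% parameters) %>%
    select(all_of(key), average = "value")
  pairs <- inner_join(straight, avg, by = key) %>%
    mutate(diff = .data$straight - .data$average,
           mean_pair = (.data$straight + .data$average) / 2)
  counts <- pairs %>% dplyr::count(.data$parameter)
  if (nrow(counts) == 0 || any(counts$n < 2) ||
    !all(parameters %in% counts$parameter)) {
    abort("Fewer than 2 matched straight/average pairs for some parameter.",
      class = "lungesym_error_too_few_pairs"
    )
  }
  out <- pairs %>%
    group_by(.data$parameter) %>%
    summarise(
      bias = mean(.data$diff), sd = sd(.data$diff),
      band = 2 * sd(.data$diff), n_pairs = dplyr::n(), .groups = "drop"
    ) %>%
    arrange(match(.data$parameter, parameters))
  attr(out, "pairs") <- pairs
  class(out) <- c("lungesym_loa", class(out))
  out
}

#' @export
tidy.lungesym_loa <- function(x, ...) {
  as_tibble(unclass(x)[c("parameter", "bias", "sd", "band", "n_pairs")])
}

#' @export
autoplot.lungesym_loa <- function(object, ...) {
  pairs <- attr(object, "pairs")
  stats <- tidy(object)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean_pair, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(
      data = stats,
      ggplot2::aes(yintercept = .data$bias), linetype = 1
    ) +
    ggplot2::geom_hline(
      data = stats,
      ggplot2::aes(yintercept = .data$bias + .data$band), linetype = 2
    ) +
    ggplot2::geom_hline(
      data = stats,
      ggplot2::aes(yintercept = .data$bias - .data$band), linetype = 2
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(
      x = "Mean of straight-line and average-rein [mm]",
      y = "Straight-line - average-rein [mm]",
      title = "Limits of agreement"
    )
}

#' Ordinary least-squares trend line
#'
#' Slope, intercept and R^2 (squared Pearson correlation) of `y` regressed
#' on `x`. Requires at least 3 points and non-constant `x`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return One-row tibble: `slope`, `intercept`, `r2`, `n`.
#' @export
#' @examples
#' linear_trend(0:2, c(0, 1, 3)) # slope 1.5, intercept -1/6
linear_trend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Need at least 3 points for a trend line.", class = "lungesym_error_trend")
  }
  if (sd(x) == 0) {
    abort("`x` is constant; trend line undefined.", class = "lungesym_error_trend")
  }
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else stats::cor(x, y)
  tibble(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = r^2, n = length(x)
  )
}

#' Straight-line vs rein trend fits for all parameters
#'
#' For every parameter, fits trend lines of average-, inside- and
#' outside-rein asymmetry (y) against the matching straight-line asymmetry
#' (x) of the same horse, surface and speed. Slopes near 1 indicate rein
#' values similar to the straight line; slopes below 1 indicate reduced
#' asymmetry on the rein.
#'
#' @param normalized Long normalized tibble (from [normalize_asymmetry()]).
#' @param parameters Parameters to fit.
#' @return Object of class `lungesym_trends`: tibble `parameter`,
#'   `comparison` (`average`/`inside`/`outside`), `slope`, `intercept`,
#'   `r2`, `n`; matched points kept in the `points` attribute.
#' @export
#' @examples
#' norm <- normalize_asymmetry(simulate_study(study_effects(n_horses = 6), seed = 1))
#' straight_vs_rein_trends(norm)
straight_vs_rein_trends <- function(normalized, parameters = asym_parameters()) {
  key <- c("horse", "surface", "speed", "parameter")
  straight <- normalized %>%
    filter(.data$direction == "straight", .data$parameter %in% parameters) %>%
    select(all_of(key), straight = "value")
  reins <- normalized %>%
    filter(.data$direction %in% c("average", "inside", "outside"),
      .data$parameter %in% parameters) %>%
    select(all_of(key), comparison = "direction", rein_value = "value")
  points <- inner_join(straight, reins, by = key)
  out <- points %>%
    group_by(.data$parameter, .data$comparison) %>%
    summarise(
      linear_trend(.data$straight, .data$rein_value), .groups = "drop"
    ) %>%
    arrange(match(.data$parameter, parameters), .data$comparison)
  attr(out, "points") <- points
  class(out) <- c("lungesym_trends", class(out))
  out
}

#' @export
tidy.lungesym_trends <- function(x, ...) {
  as_tibble(unclass(x)[c("parameter", "comparison", "slope", "intercept", "r2", "n")])
}

#' @export
autoplot.lungesym_trends <- function(object, ...) {
  points <- attr(object, "points")
  ggplot2::ggplot(
    points,
    ggplot2::aes(x = .data$straight, y = .data$rein_value, colour = .data$comparison)
  ) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(
      x = "Straight-line asymmetry [mm]", y = "Rein asymmetry [mm]",
      colour = NULL, title = "Straight-line vs rein asymmetry"
    )
}
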