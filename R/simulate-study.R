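#' Simulate a condition-level lunging study
#'
#' Generates one asymmetry record per horse x surface x speed x direction
#' under the generative structure the downstream mixed models assume. For
#' every asymmetry parameter `p`:
#'
#' `value = baseline_p + horse intercept + surface_effect * 1[hard] +`
#' `speed_effect * 1[fast] + dir * lean_gain * body_lean_angle(v(speed), r)`
#' `+ residual`
#'
#' with `dir = +1` on the left rein, `-1` on the right rein and `0` on the
#' straight, so circle-induced asymmetry is an exact mirror between reins at
#' equal speed (after sign normalization it appears as `+delta` on the
#' inside and `-delta` on the outside rein, whatever the horse's preexisting
#' side). Horse intercepts are `N(0, horse_sd)` per horse and parameter,
#' residuals `N(0, residual_sd)` per record and parameter. Stride time gets
#' its own additive model (see [study_effects()]).
#'
#' @param effects A [study_effects()] object.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A tibble with one row per horse x condition: `horse`, `surface`,
#'   `speed`, `direction`, the 11 parameter columns \[mm\], `stride_time`
#'   \[ms\] and `n_strides`.
#' @export
#' @examples
#' records <- simulate_study(study_effects(n_horses = 4), seed = 1)
#' head(records)
simulate_study <- function(effects, seed = 1) {
  stopifnot(inherits(effects, "study_effects"))
  pars <- asym_parameters()
  conds <- effects$conditions
  n_h <- effects$n_horses

  withr::with_seed(child_seed(seed, 1), {
    horse_int <- matrix(rnorm(n_h * length(pars), sd = effects$horse_sd),
      nrow = n_h, dimnames = list(NULL, pars)
    )
    horse_int_st <- rnorm(n_h, sd = effects$stride_time_horse_sd)

    grid <- tidyr::expand_grid(horse = sprintf("horse%02d", seq_len(n_h)), conds)
    hix <- as.integer(sub("horse", "", grid$horse))

    dir_sign <- c(straight = 0, left = 1, right = -1)[grid$direction]
    lean <- effects$lean_gain *
      body_lean_angle(effects$speed_mps[grid$speed], effects$radius) * dir_sign

    vals <- sapply(pars, function(p) {
      effects$baseline[[p]] + horse_int[hix, p] +
        effects$surface_effect * (grid$surface == "hard") +
        effects$speed_effect * (grid$speed == "fast") +
        lean +
        rnorm(nrow(grid), sd = effects$residual_sd)
    })

    stride_time <- effects$stride_time_base +
      horse_int_st[hix] +
      effects$stride_time_surface / 2 * ifelse(grid$surface == "hard", 1, -1) +
      effects$stride_time_speed / 2 * ifelse(grid$speed == "fast", 1, -1) +
      effects$stride_time_direction[grid$direction] +
      rnorm(nrow(grid), sd = effects$stride_time_sd)

    dplyr::bind_cols(grid, as_tibble(vals)) %>%
      mutate(stride_time = as.numeric(stride_time), n_strides = 30L)
  })
}
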