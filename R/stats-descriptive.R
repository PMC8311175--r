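# Descriptive statistics of preexisting (straight-line) asymmetry.

#' Descriptive summary of straight-line asymmetry
#'
#' Per-parameter mean, SD, mean of absolute values, minimum and maximum of
#' the straight-line records, plus the number of horses categorized as
#' left- or right-sided (sign of each horse's mean straight-line value
#' under the left-minus-right convention). SDs use the n-1 denominator; a
#' single observation is reported as SD 0 with `n = 1`.
#'
#' @param records Wide condition table with straight-line rows.
#' @param parameters Parameters to summarize (default [asym_parameters()]).
#' @return Tibble with one row per parameter: `parameter`, `n`, `mean`,
#'   `sd`, `mean_abs`, `min`, `max`, `n_left`, `n_right`.
#' @export
#' @examples
#' describe_asymmetry(simulate_study(study_effects(n_horses = 5), seed = 1))
describe_asymmetry <- function(records, parameters = asym_parameters()) {
  straight <- records %>% filter(.data$direction == "straight")
  if (nrow(straight) == 0) {
    abort("No straight-line records.", class = "lungesym_error_empty")
  }
  sides <- preexisting_sign(records, parameters) %>%
    group_by(.data$parameter) %>%
    summarise(
      n_left = sum(.data$side == "left"),
      n_right = sum(.data$side == "right"), .groups = "drop"
    )
  straight %>%
    tidyr::pivot_longer(all_of(parameters),
      names_to = "parameter", values_to = "value"
    ) %>%
    group_by(.data$parameter) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      mean_abs = mean(abs(.data$value)),
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) %>%
    left_join(sides, by = "parameter") %>%
    arrange(match(.data$parameter, parameters))
}

#' Intra-horse straight-line variation
#'
#' For each horse with at least two straight-line conditions, deviations of
#' each straight-line value from that horse's straight-line mean are
#' computed; the SD (n-1) of the pooled deviations across all eligible
#' horses is the intra-horse SD reported per parameter. Horses with a
#' single straight condition are excluded; if none remain, an error is
#' raised.
#'
#' @param records Wide condition table.
#' @param parameters Parameters to assess (default [asym_parameters()]).
#' @return List with `pooled` (tibble `parameter`, `intra_horse_sd` \[mm\],
#'   `n_deviations`, `n_horses`) and `per_horse` (tibble `horse`,
#'   `parameter`, `sd`, `n`) for diagnostics.
#' @export
#' @examples
#' intra_horse_sd(simulate_study(study_effects(n_horses = 5), seed = 1))$pooled
intra_horse_sd <- function(records, parameters = asym_parameters()) {
  devs <- records %>%
    filter(.data$direction == "straight") %>%
    tidyr::pivot_longer(all_of(parameters),
      names_to = "parameter", values_to = "value"
    ) %>%
    group_by(.data$horse, .data$parameter) %>%
    filter(dplyr::n() >= 2) %>%
    mutate(dev = .data$value - mean(.data$value)) %>%
    ungroup()
  if (nrow(devs) == 0) {
    abort("No horse has two or more straight-line conditions.",
      class = "lungesym_error_empty"
    )
  }
  pooled <- devs %>%
    group_by(.data$parameter) %>%
    summarise(
      intra_horse_sd = sd(.data$dev),
      n_deviations = dplyr::n(),
      n_horses = dplyr::n_distinct(.data$horse),
      .groups = "drop"
    ) %>%
    arrange(match(.data$parameter, parameters))
  per_horse <- devs %>%
    group_by(.data$horse, .data$parameter) %>%
    summarise(sd = sd(.data$dev), n = dplyr::n(), .groups = "drop")
  list(pooled = pooled, per_horse = per_horse)
}
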