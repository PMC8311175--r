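# Two-step normalization: sign inversion by preexisting straight-line
# asymmetry, inside/outside rein relabeling, and average-rein combination.
#
# Relabeling is per parameter (a horse can be left-sided for HDmin and
# right-sided for HDmax), so normalized data are a long (tidy) table keyed
# by horse x surface x speed x rein x parameter.

#' Preexisting asymmetry sign per horse and parameter
#'
#' The sign of a horse's mean straight-line value of each parameter, the
#' reference for the sign normalization. Horses without a straight-line
#' record cannot be normalized and raise an error (matching the study's
#' inclusion rule of at least one straight assessment). An exact-zero mean
#' is treated as positive (no inversion) with a warning.
#'
#' @param records Wide condition table: columns `horse`, `surface`, `speed`,
#'   `direction` and the 11 parameter columns.
#' @param parameters Parameters to use (default [asym_parameters()]).
#' @return Tibble `horse`, `parameter`, `pre_mean` \[mm\], `sign` (+1/-1),
#'   `side` (`"left"`/`"right"`; positive mean under the left-minus-right
#'   convention means left-sided).
#' @export
preexisting_sign <- function(records, parameters = asym_parameters()) {
  stopifnot(all(c("horse", "direction") %in% names(records)))
  no_straight <- setdiff(
    unique(records$horse),
    unique(records$horse[records$direction == "straight"])
  )
  if (length(no_straight) > 0) {
    abort(
      paste0(
        "No straight-line record for horse(s): ",
        paste(no_straight, collapse = ", "),
        ". Horses need at least one straight assessment to be normalized."
      ),
      class = "lungesym_error_no_straight"
    )
  }
  out <- records %>%
    filter(.data$direction == "straight") %>%
    tidyr::pivot_longer(all_of(parameters),
      names_to = "parameter", values_to = "value"
    ) %>%
    group_by(.data$horse, .data$parameter) %>%
    summarise(pre_mean = mean(.data$value), .groups = "drop") %>%
    mutate(
      sign = ifelse(.data$pre_mean < 0, -1, 1),
      side = ifelse(.data$sign > 0, "left", "right")
    )
  if (any(out$pre_mean == 0)) {
    warn("Exact-zero preexisting mean: treated as positive (no inversion).")
  }
  out
}

#' Sign-normalize asymmetry values against preexisting asymmetry
#'
#' For every horse and parameter whose mean straight-line value is negative,
#' all values of that parameter (straight and lunge alike) are inverted, so
#' that after normalization positive values mean "same direction as the
#' preexisting asymmetry" and negative values mean the horse has switched
#' sides. Each parameter is handled independently. The operation is
#' idempotent: normalizing an already-normalized dataset changes nothing.
#'
#' @param records Wide condition table (`horse`, `surface`, `speed`,
#'   `direction`, 11 parameter columns), or an already-long normalized
#'   table from a previous call.
#' @param parameters Parameters to normalize (default [asym_parameters()]).
#' @return Long tibble: `horse`, `surface`, `speed`, `rein` (original
#'   `straight`/`left`/`right`), `parameter`, `value` \[mm\], `inverted`
#'   (logical), `side` (preexisting side label).
#' @export
#' @examples
#' rec <- simulate_study(study_effects(n_horses = 3), seed = 1)
#' norm <- normalize_signs(rec)
normalize_signs <- function(records, parameters = asym_parameters()) {
  if (all(c("parameter", "value", "rein") %in% names(records))) {
    # already long: re-derive signs from the (normalized) straight means
    long <- records %>% select(-dplyr::any_of(c("inverted", "side", "direction")))
    wideish <- long %>% rename(direction = "rein")
  } else {
    wideish <- records
    long <- records %>%
      tidyr::pivot_longer(all_of(parameters),
        names_to = "parameter", values_to = "value"
      ) %>%
      rename(rein = "direction") %>%
      select("horse", "surface", "speed", "rein", "parameter", "value")
  }
  signs <- preexisting_sign(
    if ("parameter" %in% names(wideish)) {
      wideish %>% tidyr::pivot_wider(names_from = "parameter", values_from = "value")
    } else {
      wideish
    },
    parameters
  )
  long %>%
    left_join(select(signs, "horse", "parameter", "sign", "side"),
      by = c("horse", "parameter")
    ) %>%
    mutate(value = .data$value * .data$sign, inverted = .data$sign < 0) %>%
    select(-"sign")
}

#' Relabel reins as inside/outside relative to preexisting asymmetry
#'
#' The left rein of a left-sided horse puts the limb attributed to the
#' preexisting asymmetry on the inside of the circle, so it is labelled
#' `inside` and the right rein `outside` (vice versa for right-sided
#' horses). Straight rows keep direction `straight`. Side labels are per
#' parameter, following the sign normalization.
#'
#' @param normalized Long normalized tibble from [normalize_signs()] (must
#'   carry the `side` column).
#' @return The input with a `direction` column
#'   (`straight`/`inside`/`outside`).
#' @export
assign_inside_outside <- function(normalized) {
  if (!"side" %in% names(normalized) || any(is.na(normalized$side))) {
    abort("Missing side labels; run normalize_signs() first.",
      class = "lungesym_error_no_side"
    )
  }
  normalized %>%
    mutate(direction = dplyr::case_when(
      .data$rein == "straight" ~ "straight",
      .data$rein == .data$side ~ "inside",
      TRUE ~ "outside"
    ))
}

#' Combine inside and outside rein into average-rein records
#'
#' For each horse x surface x speed x parameter with both an inside and an
#' outside record, appends a row with direction `average` holding their
#' arithmetic mean. Conditions with only one rein produce no average row
#' (silently excluded; the count is reported via a message and the
#' `n_unmatched` attribute).
#'
#' @param normalized Long normalized tibble with a `direction` column from
#'   [assign_inside_outside()].
#' @param quiet Suppress the unmatched-condition message.
#' @return The input plus `direction == "average"` rows (`rein` is `NA` for
#'   those).
#' @export
average_rein <- function(normalized, quiet = FALSE) {
  if (!"direction" %in% names(normalized)) {
    abort("Run assign_inside_outside() before average_rein().",
      class = "lungesym_error_no_side"
    )
  }
  reins <- normalized %>% filter(.data$direction %in% c("inside", "outside"))
  avg <- reins %>%
    group_by(.data$horse, .data$surface, .data$speed, .data$parameter) %>%
    summarise(
      value = mean(.data$value), n_reins = dplyr::n(),
      inverted = any(.data$inverted), side = .data$side[1], .groups = "drop"
    )
  n_unmatched <- sum(avg$n_reins < 2)
  if (n_unmatched > 0 && !quiet) {
    inform(paste0(n_unmatched, " condition-parameter(s) lacked one rein; no average row."))
  }
  avg <- avg %>%
    filter(.data$n_reins == 2) %>%
    mutate(rein = NA_character_, direction = "average") %>%
    select(-"n_reins")
  out <- bind_rows(normalized, avg)
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Full normalization chain
#'
#' Convenience wrapper: [normalize_signs()], [assign_inside_outside()],
#' [average_rein()].
#'
#' @inheritParams normalize_signs
#' @param quiet Passed to [average_rein()].
#' @return Long normalized tibble with directions
#'   `straight`/`inside`/`outside`/`average`.
#' @export
#' @examples
#' norm <- normalize_asymmetry(simulate_study(study_effects(n_horses = 3), seed = 1))
normalize_asymmetry <- function(records, parameters = asym_parameters(),
                                quiet = FALSE) {
  records %>%
    normalize_signs(parameters) %>%
    assign_inside_outside() %>%
    average_rein(quiet = quiet)
}

#' Flag preexisting asymmetries against clinical thresholds
#'
#' Marks head and pelvic parameters whose absolute straight-line value
#' strictly exceeds the clinical screening thresholds (defaults: 6 mm for
#' head, 3 mm for pelvic movement, applied to sacrum and tuber coxae
#' parameters alike). Withers parameters carry no published threshold and
#' are not flagged.
#'
#' @param records Wide condition table with straight-line rows.
#' @param head_threshold,pelvis_threshold Thresholds \[mm\].
#' @return Tibble `horse`, `parameter`, `value` \[mm\] (mean straight-line),
#'   `flag` (logical).
#' @export
#' @examples
#' rec <- simulate_study(study_effects(n_horses = 3), seed = 1)
#' flag_preexisting(rec)
flag_preexisting <- function(records, head_threshold = 6, pelvis_threshold = 3) {
  head_pars <- c("HDmin", "HDmax", "HDup")
  pelvis_pars <- c("PDmin", "PDmax", "PDup", "HHD", "RD")
  records %>%
    filter(.data$direction == "straight") %>%
    tidyr::pivot_longer(all_of(c(head_pars, pelvis_pars)),
      names_to = "parameter", values_to = "value"
    ) %>%
    group_by(.data$horse, .data$parameter) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    mutate(flag = abs(.data$value) > ifelse(.data$parameter %in% head_pars,
      head_threshold, pelvis_threshold
    ))
}
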