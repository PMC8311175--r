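# The eleven movement asymmetry indices and their condition-level summary.

#' Per-stride movement asymmetry indices
#'
#' Computes the eleven signed asymmetry indices from a tidy per-stride
#' feature table. Every index is the left-associated minus the
#' right-associated quantity: for head (`HD*`), withers (`WD*`) and pelvis
#' (`PD*`) the differences of the per-step displacement minima, maxima and
#' upward amplitudes; `HHD` the difference between the left tuber coxae
#' upward amplitude during right-hind stance and the right tuber coxae
#' upward amplitude during left-hind stance; `RD` the left-minus-right
#' difference in tuber coxae range of motion. Positive values denote the
#' pattern conventionally attributed to the left side; the convention is
#' global and used consistently by the normalization step, which is all the
#' downstream analysis requires. Strides with an incomplete feature set are
#' skipped (never partially computed); the count is in the `n_skipped`
#' attribute.
#'
#' @param features Tidy feature tibble from [extract_stride_features()]:
#'   columns `stride_id`, `landmark`, `feature`, `side`, `value_mm`.
#' @return Tibble with one row per complete stride: `stride_id` plus the 11
#'   index columns \[mm\].
#' @export
#' @examples
#' f <- tidyr::expand_grid(stride_id = 1L,
#'   landmark = c("poll", "withers", "sacrum"),
#'   feature = c("min", "max", "up"), side = c("left", "right"))
#' f$value_mm <- ifelse(f$side == "left", 1, 0)
#' f2 <- tibble::tibble(stride_id = 1L,
#'   landmark = c("left_tuber_coxae", "left_tuber_coxae",
#'                "right_tuber_coxae", "right_tuber_coxae"),
#'   feature = c("up_contra", "rom", "up_contra", "rom"),
#'   side = c("left", "left", "right", "right"), value_mm = c(25, 40, 20, 40))
#' stride_asymmetry(dplyr::bind_rows(f, f2))
stride_asymmetry <- function(features) {
  stopifnot(all(c("stride_id", "landmark", "feature", "side", "value_mm") %in%
    names(features)))
  prefix <- c(poll = "HD", withers = "WD", sacrum = "PD")

  long <- features %>%
    mutate(index = dplyr::case_when(
      .data$landmark %in% MIDLINE_LANDMARKS ~ paste0(prefix[.data$landmark], .data$feature),
      .data$feature == "up_contra" ~ "HHD",
      .data$feature == "rom" ~ "RD"
    )) %>%
    group_by(.data$stride_id, .data$index, .data$side) %>%
    summarise(value_mm = list(.data$value_mm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "side", values_from = "value_mm")
  for (col in c("left", "right")) {
    if (!col %in% names(long)) long[[col]] <- vector("list", nrow(long))
  }
  long <- long %>%
    mutate(
      n_l = purrr::map_int(.data$left, length),
      n_r = purrr::map_int(.data$right, length)
    )

  ok_ids <- long %>%
    group_by(.data$stride_id) %>%
    summarise(
      ok = dplyr::n() == 11L && all(.data$n_l == 1L) && all(.data$n_r == 1L),
      .groups = "drop"
    )
  n_skipped <- sum(!ok_ids$ok)

  out <- long %>%
    semi_join(filter(ok_ids, .data$ok), by = "stride_id") %>%
    mutate(value = purrr::map_dbl(.data$left, 1) - purrr::map_dbl(.data$right, 1)) %>%
    select("stride_id", "index", "value") %>%
    tidyr::pivot_wider(names_from = "index", values_from = "value")
  if (nrow(out) > 0) {
    out <- out %>% select("stride_id", all_of(asym_parameters())) %>%
      arrange(.data$stride_id)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Summarize a condition by per-stride medians
#'
#' Median of each asymmetry index and of stride time across all retained
#' strides of one assessment condition, the condition-level record the
#' normalization and statistics stages consume.
#'
#' @param stride_indices Per-stride index tibble from [stride_asymmetry()].
#' @param stride_times Stride durations \[ms\] of the retained strides.
#' @param min_strides Minimum stride count (default 15).
#' @param condition Optional named list/tibble of labels (`horse`,
#'   `surface`, `speed`, `direction`) prepended to the record.
#' @return One-row tibble: condition labels, the 11 median indices \[mm\],
#'   `stride_time` \[ms\], `n_strides`.
#' @export
condition_summary <- function(stride_indices, stride_times, min_strides = 15,
                              condition = NULL) {
  n <- nrow(stride_indices)
  if (n < min_strides) {
    lab <- if (is.null(condition)) "" else paste0(
      " (", paste(unlist(condition), collapse = "/"), ")"
    )
    abort(
      paste0("Condition", lab, " has ", n, " strides; ", min_strides, " required."),
      class = "lungesym_error_too_few_strides"
    )
  }
  meds <- stride_indices %>%
    summarise(across(all_of(asym_parameters()), median))
  rec <- dplyr::bind_cols(
    meds,
    tibble(stride_time = median(stride_times), n_strides = n)
  )
  if (!is.null(condition)) rec <- dplyr::bind_cols(as_tibble(condition), rec)
  rec
}
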