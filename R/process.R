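# From raw five-landmark traces to one condition-level asymmetry record.

#' Process a five-landmark trial into an asymmetry record
#'
#' The full kinematic chain for one assessment condition: rotate each trace
#' into the horse/gravity frame, double-integrate to vertical displacement,
#' segment strides on the sacrum, attribute diagonal steps (ground-truth
#' labels when the trial carries a simulator sidecar and `use_truth_steps`
#' is `TRUE`, otherwise tuber coxae phase), extract per-stride features,
#' compute the eleven indices, and summarize the condition by medians.
#' Strides starting within 1.5 stride periods of either record edge are
#' excluded to keep filter transients out of the features.
#'
#' @param trial A `gait_trial` from [simulate_trial()], or a named list of
#'   five sensor-trace data frames (names = landmarks) as read by
#'   [read_sensor_traces()].
#' @param min_strides Minimum retained stride count (default 15).
#' @param use_truth_steps Use simulator step-side labels when available
#'   (default `TRUE`); set `FALSE` to force tuber coxae phase attribution.
#' @param condition Optional named list of labels (`horse`, `surface`,
#'   `speed`, `direction`) for the output record.
#' @return Object of class `gait_processed`: list with `record` (one-row
#'   condition tibble), `stride_indices`, `features`, `strides`,
#'   `displacement`, and a `log` of stride counts and drops.
#' @export
#' @examples
#' trial <- simulate_trial(trot_params(duration = 15), seed = 1)
#' pr <- process_trial(trial, min_strides = 10)
#' pr$record
process_trial <- function(trial, min_strides = 15, use_truth_steps = TRUE,
                          condition = NULL) {
  if (inherits(trial, "gait_trial")) {
    traces <- lapply(trial$landmarks, function(s) s$trace)
    truth_steps <- trial$landmarks[[1]]$truth$step_side
  } else {
    traces <- trial
    truth_steps <- NULL
  }
  missing <- setdiff(LANDMARKS, names(traces))
  if (length(missing) > 0) {
    abort(paste0("Missing landmark traces: ", paste(missing, collapse = ", ")),
      class = "lungesym_error_schema"
    )
  }
  fs <- attr(traces[["sacrum"]], "sample_rate") %||%
    round(1 / median(diff(traces[["sacrum"]]$t)))

  acc <- lapply(traces[LANDMARKS], rotate_to_horse_frame)
  f_stride <- estimate_stride_frequency(acc[["sacrum"]], fs)
  disp <- lapply(acc, integrate_to_displacement, sample_rate = fs,
    stride_freq_hint = f_stride)

  # segmentation runs on the broadband displacement (tone bands clip the
  # sidebands of strongly jittered strides); features use the tone-band
  # displacement above
  disp_seg <- integrate_to_displacement(acc[["sacrum"]], fs, f_stride,
    tone_bands = FALSE)
  strides <- segment_strides(disp_seg, fs, min_strides = min_strides)

  # drop strides inside the filter transient zone at the record edges
  n <- length(disp[["sacrum"]])
  guard <- 1.5 * fs / f_stride
  edge_ok <- strides$start > guard & strides$end < n - guard
  strides <- strides[edge_ok, ]
  if (nrow(strides) < min_strides) {
    abort(
      paste0("Only ", nrow(strides), " strides outside the record edges; ",
        min_strides, " required."),
      class = "lungesym_error_too_few_strides"
    )
  }

  step_side <- if (use_truth_steps && !is.null(truth_steps)) {
    truth_steps
  } else {
    attribute_steps(disp[["left_tuber_coxae"]], disp[["right_tuber_coxae"]],
      fs, f_stride)
  }

  displacement <- purrr::imap(disp, function(d, lm) {
    tibble(sample = seq_along(d), landmark = lm, disp_mm = d)
  }) %>% bind_rows()

  features <- extract_stride_features(displacement, strides, step_side)
  idx <- stride_asymmetry(features)
  kept <- strides %>% semi_join(idx, by = "stride_id")
  rec <- condition_summary(idx, kept$stride_time,
    min_strides = min_strides, condition = condition)

  structure(
    list(
      record = rec, stride_indices = idx, features = features,
      strides = strides, displacement = displacement,
      log = list(
        n_strides = nrow(idx),
        n_discarded_segmentation = attr(strides, "n_discarded"),
        n_dropped_features = attr(features, "n_dropped"),
        n_skipped_indices = attr(idx, "n_skipped"),
        stride_freq = f_stride
      )
    ),
    class = "gait_processed"
  )
}

#' @export
print.gait_processed <- function(x, ...) {
  cat("<gait_processed> ", x$log$n_strides, " strides (",
    x$log$n_discarded_segmentation, " discarded, ",
    x$log$n_skipped_indices, " incomplete), stride freq ",
    round(x$log$stride_freq, 3), " Hz\n",
    sep = ""
  )
  print(x$record)
  invisible(x)
}
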