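# CSV I/O with explicit schemas, study configuration.

TRACE_COLS <- c("t", "ax", "ay", "az", "roll", "pitch", "yaw")

#' Read one sensor trace CSV
#'
#' Columnar text schema: `t` \[s\], `ax, ay, az` \[m/s^2\], `roll, pitch,
#' yaw` \[deg\], header required. Sampling must be uniform within 1%
#' relative tolerance; the rate is inferred from the time column and, if a
#' `sample_rate` is supplied, checked against it.
#'
#' @param path CSV file.
#' @param landmark Landmark name; default inferred from the file name
#'   (without extension).
#' @param sample_rate Expected rate \[Hz\] (optional check).
#' @return Trace tibble with attributes `landmark` and `sample_rate`.
#' @export
read_sensor_trace <- function(path, landmark = NULL, sample_rate = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(TRACE_COLS, names(df))
  if (length(missing) > 0) {
    abort(paste0("Trace ", path, " is missing columns: ",
      paste(missing, collapse = ", ")), class = "lungesym_error_schema")
  }
  if (nrow(df) < 2) {
    abort(paste0("Trace ", path, " has fewer than 2 samples."),
      class = "lungesym_error_schema"
    )
  }
  dt <- diff(df$t)
  if (any(dt <= 0) || (max(dt) - min(dt)) / median(dt) > 0.01) {
    abort(paste0("Trace ", path, " is not uniformly sampled (tolerance 1%)."),
      class = "lungesym_error_schema"
    )
  }
  rate <- 1 / median(dt)
  if (!is.null(sample_rate) && abs(rate - sample_rate) / sample_rate > 0.01) {
    abort(paste0("Trace ", path, " sampled at ", round(rate, 2),
      " Hz; expected ", sample_rate, " Hz."), class = "lungesym_error_schema")
  }
  landmark <- landmark %||% sub("\\.csv$", "", basename(path))
  if (!landmark %in% LANDMARKS) {
    abort(paste0("Unknown landmark '", landmark, "'. Valid: ",
      paste(LANDMARKS, collapse = ", ")), class = "lungesym_error_landmark")
  }
  out <- as_tibble(df[TRACE_COLS])
  attr(out, "landmark") <- landmark
  attr(out, "sample_rate") <- rate
  out
}

#' Read a directory of five landmark traces
#'
#' Expects one `<landmark>.csv` per landmark.
#'
#' @param dir Directory containing the five CSVs.
#' @param sample_rate Expected rate \[Hz\] (optional check).
#' @return Named list of trace tibbles.
#' @export
read_sensor_traces <- function(dir, sample_rate = NULL) {
  paths <- file.path(dir, paste0(LANDMARKS, ".csv"))
  missing <- LANDMARKS[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("Missing trace files in ", dir, ": ",
      paste(missing, collapse = ", ")), class = "lungesym_error_schema")
  }
  out <- lapply(seq_along(paths), function(i) {
    read_sensor_trace(paths[i], LANDMARKS[i], sample_rate)
  })
  names(out) <- LANDMARKS
  out
}

#' Write a sensor trace CSV
#'
#' @param trace Trace tibble (columns `t, ax, ay, az, roll, pitch, yaw`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[TRACE_COLS], path)
  invisible(path)
}

RECORD_KEY <- c("horse", "surface", "speed", "direction")

validate_levels <- function(df, col, allowed) {
  bad <- which(!(df[[col]] %in% allowed))
  if (length(bad) > 0) {
    abort(paste0(
      "Row ", bad[1], ": invalid ", col, " '", df[[col]][bad[1]],
      "'. Allowed: ", paste(allowed, collapse = ", "), "."
    ), class = "lungesym_error_schema")
  }
}

#' Read / write a condition-level asymmetry table
#'
#' The interchange schema between the processing, normalization and
#' statistics stages: one row per horse x surface x speed x direction with
#' the 11 parameter columns \[mm\], `stride_time` \[ms\] and `n_strides`.
#' Factor levels are validated row by row; write-then-read is the identity
#' (values round-trip losslessly at full double precision).
#'
#' @param path CSV path.
#' @param normalized Allow normalized direction levels
#'   (`inside`/`outside`/`average`) in addition to the raw ones.
#' @return `read_condition_table()`: validated tibble.
#' @export
read_condition_table <- function(path, normalized = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) {
    abort(paste0(path, " contains no records."), class = "lungesym_error_empty")
  }
  long <- "parameter" %in% names(df)
  need <- if (long) c(RECORD_KEY[1:3], "parameter", "value") else
    c(RECORD_KEY, asym_parameters(), "stride_time", "n_strides")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing columns: ", paste(missing, collapse = ", ")),
      class = "lungesym_error_schema"
    )
  }
  validate_levels(df, "surface", SURFACES)
  validate_levels(df, "speed", SPEEDS)
  if ("direction" %in% names(df)) {
    validate_levels(df, "direction",
      if (normalized || long) NORM_DIRECTIONS else RAW_DIRECTIONS)
  }
  if (long) validate_levels(df, "parameter", asym_parameters())
  as_tibble(df)
}

#' @param records Condition table (wide, or long normalized with
#'   `parameter`/`value` columns).
#' @rdname read_condition_table
#' @export
write_condition_table <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' Study configuration
#'
#' Declarative configuration for [run_pipeline()]. Values can come from a
#' YAML file; explicit arguments override file values, which override the
#' defaults.
#'
#' @param file Optional YAML file.
#' @param ... Overrides: `out_dir`, `seed`, `sample_rate` \[Hz\],
#'   `min_strides`, `head_threshold` \[mm\], `pelvis_threshold` \[mm\],
#'   `radius` \[m\], `lean_gain` \[mm/deg\], `n_horses`, `duration` \[s\],
#'   `noise_sd` \[mm\], `stride_time_jitter`, `reml`,
#'   `drop_singular_random`.
#' @return Object of class `study_config` (a named list).
#' @export
#' @examples
#' study_config(n_horses = 3, out_dir = tempdir())
study_config <- function(file = NULL, ...) {
  defaults <- list(
    out_dir = "lungesym_out", seed = 1L, sample_rate = 100,
    min_strides = 15, head_threshold = 6, pelvis_threshold = 3,
    radius = 7.5, lean_gain = 0.8, speed_mps = c(slow = 3, fast = 4),
    n_horses = 5, duration = 25, noise_sd = 2, stride_time_jitter = 0.05,
    reml = TRUE, drop_singular_random = FALSE
  )
  cfg <- defaults
  if (!is.null(file)) {
    fromfile <- yaml::read_yaml(file)
    if ("speed_mps" %in% names(fromfile)) {
      fromfile$speed_mps <- unlist(fromfile$speed_mps)
    }
    cfg[names(fromfile)] <- fromfile
  }
  overrides <- list(...)
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")),
      class = "lungesym_error_config"
    )
  }
  if (cfg$sample_rate <= 0 || cfg$min_strides < 1 || cfg$radius <= 0) {
    abort("Invalid config: sample_rate, min_strides and radius must be positive.",
      class = "lungesym_error_config"
    )
  }
  structure(cfg, class = "study_config")
}
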