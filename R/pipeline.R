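# End-to-end pipeline driver: simulate -> process -> normalize -> analyze
# -> report, all artifacts as plain CSV under the configured output
# directory, deterministic for a fixed seed.

cond_id <- function(horse, surface, speed, direction) {
  paste(horse, surface, speed, direction, sep = "_")
}

pipeline_paths <- function(cfg) {
  list(
    traces = file.path(cfg$out_dir, "traces"),
    truth = file.path(cfg$out_dir, "truth.csv"),
    records = file.path(cfg$out_dir, "records.csv"),
    process_log = file.path(cfg$out_dir, "process_log.csv"),
    normalized = file.path(cfg$out_dir, "normalized.csv"),
    flags = file.path(cfg$out_dir, "preexisting_flags.csv"),
    descriptives = file.path(cfg$out_dir, "descriptives.csv"),
    intra_horse = file.path(cfg$out_dir, "intra_horse_sd.csv"),
    trends = file.path(cfg$out_dir, "trends.csv"),
    loa = file.path(cfg$out_dir, "limits_of_agreement.csv"),
    models_straight_avg = file.path(cfg$out_dir, "models_straight_avg.csv"),
    models_inside = file.path(cfg$out_dir, "models_inside.csv"),
    models_outside = file.path(cfg$out_dir, "models_outside.csv"),
    stride_time = file.path(cfg$out_dir, "stride_time_model.csv"),
    stride_time_pairwise = file.path(cfg$out_dir, "stride_time_pairwise.csv"),
    report = file.path(cfg$out_dir, "report.txt")
  )
}

stage_simulate <- function(cfg, paths) {
  effects <- study_effects(
    n_horses = cfg$n_horses, residual_sd = 0, lean_gain = 0,
    radius = cfg$radius, speed_mps = cfg$speed_mps
  )
  truths <- simulate_study(effects, seed = cfg$seed)
  dir.create(paths$traces, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(truths))) {
    row <- truths[i, ]
    tp <- trot_params(
      stride_time = row$stride_time / 1000,
      sample_rate = cfg$sample_rate,
      duration = cfg$duration,
      asym_min = c(poll = row$HDmin, withers = row$WDmin, sacrum = row$PDmin),
      asym_max = c(poll = row$HDmax, withers = row$WDmax, sacrum = row$PDmax),
      hike_diff = row$HHD, rom_diff = row$RD,
      # keep the tuber coxae range wide enough for large simulated
      # hike/range asymmetries
      tc_rom = max(35, 25 + (abs(row$HHD) + abs(row$RD)) / 2),
      noise_sd = cfg$noise_sd, stride_time_jitter = cfg$stride_time_jitter
    )
    circle <- if (row$direction == "straight") NULL else {
      circle_params(
        speed = cfg$speed_mps[[row$speed]], radius = cfg$radius,
        direction = row$direction, lean_gain = cfg$lean_gain
      )
    }
    trial <- simulate_trial(tp, seed = child_seed(cfg$seed, i), circle = circle)
    d <- file.path(paths$traces, cond_id(row$horse, row$surface, row$speed, row$direction))
    dir.create(d, showWarnings = FALSE)
    for (lm in LANDMARKS) {
      write_sensor_trace(trial$landmarks[[lm]]$trace, file.path(d, paste0(lm, ".csv")))
    }
  }
  write_condition_table(truths, paths$truth)
  invisible(truths)
}

stage_process <- function(cfg, paths) {
  dirs <- list.dirs(paths$traces, recursive = FALSE)
  if (length(dirs) == 0) {
    abort("No trace directories found; run the simulate stage first (or point the config at existing traces).",
      class = "lungesym_error_dependency"
    )
  }
  recs <- list()
  logs <- list()
  for (d in dirs) {
    parts <- strsplit(basename(d), "_")[[1]]
    cond <- list(horse = parts[1], surface = parts[2], speed = parts[3],
      direction = parts[4])
    traces <- read_sensor_traces(d, sample_rate = cfg$sample_rate)
    pr <- process_trial(traces, min_strides = cfg$min_strides,
      use_truth_steps = FALSE, condition = cond)
    recs[[length(recs) + 1]] <- pr$record
    logs[[length(logs) + 1]] <- tibble(
      condition = basename(d), n_strides = pr$log$n_strides,
      n_discarded = pr$log$n_discarded_segmentation,
      n_incomplete = pr$log$n_skipped_indices,
      stride_freq_hz = pr$log$stride_freq
    )
    inform(paste0(
      "processed ", basename(d), ": ", pr$log$n_strides, " strides (",
      pr$log$n_discarded_segmentation, " discarded)"
    ))
  }
  records <- bind_rows(recs)
  write_condition_table(records, paths$records)
  readr::write_csv(bind_rows(logs), paths$process_log)
  invisible(records)
}

stage_normalize <- function(cfg, paths) {
  if (!file.exists(paths$records)) {
    abort("records.csv not found; run the process stage first.",
      class = "lungesym_error_dependency"
    )
  }
  records <- read_condition_table(paths$records)
  norm <- normalize_asymmetry(records, quiet = TRUE)
  write_condition_table(norm, paths$normalized)
  readr::write_csv(
    flag_preexisting(records, cfg$head_threshold, cfg$pelvis_threshold),
    paths$flags
  )
  invisible(norm)
}

stage_analyze <- function(cfg, paths) {
  if (!file.exists(paths$normalized)) {
    abort("normalized.csv not found; run the normalize stage first.",
      class = "lungesym_error_dependency"
    )
  }
  records <- read_condition_table(paths$records)
  norm <- read_condition_table(paths$normalized, normalized = TRUE)

  readr::write_csv(describe_asymmetry(records), paths$descriptives)
  readr::write_csv(intra_horse_sd(records)$pooled, paths$intra_horse)
  readr::write_csv(tidy(straight_vs_rein_trends(norm)), paths$trends)
  readr::write_csv(tidy(limits_of_agreement(norm)), paths$loa)

  strip <- function(fits) select(fits, -"model")
  readr::write_csv(
    strip(fit_asymmetry_models(norm, c("straight", "average"),
      c("surface", "speed", "direction"), reml = cfg$reml)),
    paths$models_straight_avg
  )
  readr::write_csv(
    strip(fit_asymmetry_models(norm, "inside", c("surface", "speed"),
      reml = cfg$reml)),
    paths$models_inside
  )
  readr::write_csv(
    strip(fit_asymmetry_models(norm, "outside", c("surface", "speed"),
      reml = cfg$reml)),
    paths$models_outside
  )

  st <- fit_stride_time_model(records, reml = cfg$reml)
  readr::write_csv(
    tidy(st) %>% mutate(converged = st$converged, singular = st$singular),
    paths$stride_time
  )
  readr::write_csv(pairwise_direction_comparisons(st), paths$stride_time_pairwise)
  invisible(NULL)
}

stage_report <- function(cfg, paths) {
  need <- c(paths$records, paths$trends, paths$loa, paths$models_straight_avg)
  miss <- need[!file.exists(need)]
  if (length(miss) > 0) {
    abort("Analysis outputs missing; run the analyze stage first.",
      class = "lungesym_error_dependency"
    )
  }
  records <- read_condition_table(paths$records)
  loa <- readr::read_csv(paths$loa, show_col_types = FALSE)
  msa <- readr::read_csv(paths$models_straight_avg, show_col_types = FALSE)
  inside <- readr::read_csv(paths$models_inside, show_col_types = FALSE)
  outside <- readr::read_csv(paths$models_outside, show_col_types = FALSE)
  stp <- readr::read_csv(paths$stride_time_pairwise, show_col_types = FALSE)

  sig <- function(df, fac) {
    df$parameter[df$factor == fac & df$p_value < 0.05]
  }
  lines <- c(
    "Movement asymmetry analysis report",
    paste0("Records: ", nrow(records), " conditions, ",
      dplyr::n_distinct(records$horse), " horses"),
    "",
    "Limits of agreement (straight vs average rein), mm:",
    paste0("  ", loa$parameter, ": bias ", round(loa$bias, 2), ", SD ",
      round(loa$sd, 2), ", 2xSD ", round(loa$band, 2)),
    "",
    paste0("Average-rein parameters affected by speed (p<0.05): ",
      paste(sig(msa, "speed"), collapse = ", ")),
    paste0("Average-rein parameters affected by surface (p<0.05): ",
      paste(sig(msa, "surface"), collapse = ", ")),
    paste0("Inside-rein parameters affected by speed (p<0.05): ",
      paste(sig(inside, "speed"), collapse = ", ")),
    paste0("Outside-rein parameters affected by speed (p<0.05): ",
      paste(sig(outside, "speed"), collapse = ", ")),
    "",
    "Stride time pairwise direction comparisons (Bonferroni-adjusted):",
    paste0("  ", stp$level_1, " vs ", stp$level_2, ": diff ",
      round(stp$estimate, 1), " ms, p_adj ", signif(stp$p_adjusted, 3))
  )
  writeLines(lines, paths$report)
  invisible(paths$report)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in order: `simulate` (write synthetic
#' five-landmark traces for every horse x condition), `process` (traces to
#' condition records via the kinematic chain), `normalize` (sign
#' normalization, inside/outside relabeling, average rein), `analyze`
#' (descriptives, trends, limits of agreement, mixed models, stride-time
#' model) and `report` (plain-text summary). All artifacts are CSV files
#' under `config$out_dir`; a fixed seed gives byte-identical outputs. A
#' stage whose inputs are missing aborts with a stage-named dependency
#' error.
#'
#' @param config A [study_config()] (or path to a YAML config file).
#' @param stages Stages to run, in pipeline order.
#' @return Invisibly, the list of artifact paths.
#' @export
#' @examples
#' \donttest{
#' cfg <- study_config(out_dir = tempfile(), n_horses = 2, duration = 15,
#'                     min_strides = 10, noise_sd = 0.5)
#' run_pipeline(cfg, stages = c("simulate", "process"))
#' }
run_pipeline <- function(config = study_config(),
                         stages = c("simulate", "process", "normalize",
                                    "analyze", "report")) {
  if (is.character(config)) config <- study_config(file = config)
  stopifnot(inherits(config, "study_config"))
  stages <- match.arg(stages,
    c("simulate", "process", "normalize", "analyze", "report"),
    several.ok = TRUE
  )
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_paths(config)
  runners <- list(
    simulate = stage_simulate, process = stage_process,
    normalize = stage_normalize, analyze = stage_analyze,
    report = stage_report
  )
  for (s in c("simulate", "process", "normalize", "analyze", "report")) {
    if (!s %in% stages) next
    inform(paste0("[", s, "] running"))
    tryCatch(
      runners[[s]](config, paths),
      error = function(e) {
        abort(paste0("Stage '", s, "' failed: ", conditionMessage(e)),
          class = c("lungesym_error_stage", class(e)[1]), parent = e
        )
      }
    )
  }
  invisible(paths)
}
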