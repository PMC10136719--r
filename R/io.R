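session_log_columns <- c(
  "time_ms", "phase", "active_leg", "leg", "cycle_index", "cycle_fraction",
  "window", "hip_ref_deg", "hip_act_deg", "knee_ref_deg", "knee_act_deg",
  "k_hip", "b_hip", "k_knee", "b_knee"
)

#' Write a session log to CSV
#'
#' @param log An `ags_session_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  missing_cols <- setdiff(session_log_columns, names(log))
  if (length(missing_cols) > 0L) {
    stop_schema(paste0("log is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(log[session_log_columns], path, progress = FALSE)
  invisible(path)
}

#' Read and validate a session log CSV
#'
#' Checks the full column schema and the sampling-uniformity invariant:
#' within every protocol phase and leg, consecutive timestamps must differ
#' by exactly one sampling interval.
#'
#' @param path A CSV written by [write_session_log()] (or by the recording
#'   device in the same schema).
#' @return An `ags_session_log` tibble.
#' @export
read_session_log <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("file `%s` does not exist.", path))
  log <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop_schema(sprintf("cannot parse `%s`: %s", path, conditionMessage(e)))
  )
  missing_cols <- setdiff(session_log_columns, names(log))
  if (length(missing_cols) > 0L) {
    stop_schema(paste0("log is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(log) == 0L) stop_schema("log file has no rows.")

  check_stream <- function(ts) {
    ts <- sort(unique(ts))
    if (length(ts) < 2L) return(invisible(NULL))
    dt <- diff(ts)
    if (length(unique(dt)) != 1L) {
      stop_integrity(sprintf(
        "non-uniform sampling: intervals %s ms found within one phase/leg stream.",
        paste(sort(unique(dt)), collapse = ", ")
      ))
    }
  }
  for (ph in unique(log$phase)) {
    for (lg in unique(log$leg)) {
      check_stream(log$time_ms[log$phase == ph & log$leg == lg])
    }
  }
  log <- as_tibble(log)
  class(log) <- unique(c("ags_session_log", class(log)))
  log
}

#' Write a simulated study to a directory
#'
#' Serializes a study as plain text: `cohort.csv`, `clinical.csv`, one
#' rendered session log CSV per training session under `sessions/`, and a
#' `seeds.json`-style ledger (`provenance.yml`) recording the seed and the
#' main generator settings. Requires the study to have been simulated with
#' `keep_deviation = TRUE`.
#'
#' @param study An `ags_study`.
#' @param dir Output directory (created if needed).
#' @param sample_ms Sampling interval for the rendered logs; defaults to the
#'   controller configuration's value.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, sample_ms = NULL) {
  stopifnot(inherits(study, "ags_study"))
  if (is.null(sample_ms)) sample_ms <- study$config$sample_ms
  dir.create(file.path(dir, "sessions"), recursive = TRUE, showWarnings = FALSE)

  cohort_df <- select(study$cohort, -all_of("profile"))
  readr::write_csv(cohort_df, file.path(dir, "cohort.csv"), progress = FALSE)
  readr::write_csv(study$clinical, file.path(dir, "clinical.csv"), progress = FALSE)

  for (i in seq_len(nrow(study$sessions))) {
    sess <- study$sessions$session[[i]]
    log <- session_log(sess$blocks, sample_ms = sample_ms)
    write_session_log(log, file.path(dir, "sessions", sprintf(
      "p%02d_s%02d_day%02d.csv", sess$patient_id, sess$session_index, sess$day
    )))
  }

  ledger <- list(
    seed = study$seed,
    n_patients = nrow(study$cohort),
    n_sessions = nrow(study$sessions),
    sample_ms = sample_ms,
    controller = unclass(study$config),
    schedule = unclass(study$schedule)
  )
  yaml::write_yaml(ledger, file.path(dir, "provenance.yml"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' A nested configuration mirroring every tunable of the simulation and
#' analysis pipeline, with defaults equal to the package's study defaults.
#' Unknown keys are rejected, so typos cannot silently fall back to a
#' default.
#'
#' @param overrides A named (possibly nested) list of settings to override.
#' @return A list of class `ags_pipeline_config` with sections `controller`,
#'   `gait`, `cohort`, `clinical`, `schedule`, `analysis`, `io`.
#' @examples
#' cfg <- pipeline_config(list(cohort = list(n = 4)))
#' cfg$cohort$n
#' @export
pipeline_config <- function(overrides = list()) {
  defaults <- list(
    controller = unclass(controller_config()),
    gait = list(cadence = 40, rom_hip = 40, rom_knee = 60,
                offset_hip = 10, offset_knee = 30, n_windows = 30,
                is_fraction = 0.105, ms_fraction = 0.14, ts_fraction = 0.13),
    cohort = {
      cp <- unclass(cohort_params())
      cp$subphase_weights <- as.list(cp$subphase_weights)
      c(list(n = 10, seed = 20230612), cp)
    },
    clinical = unclass(clinical_params()),
    schedule = unclass(study_schedule()),
    analysis = list(
      exclusion_min = 1, last_minutes = 4, plateau_lambda_span = 3,
      plateau_rmse = 0.05, min_points = 10, alpha_enter = 0.05,
      enet_runs = 100, enet_alpha = 0.75, enet_folds = 3,
      force_threshold = 0.4, stiffness_threshold = 30
    ),
    io = list(sample_ms = 4)
  )
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "ags_pipeline_config")
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop_invalid(sprintf("config section `%s` must be a named list.", path))
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop_invalid(sprintf("unknown config key(s)%s: %s",
                         if (nzchar(path)) paste0(" in `", path, "`") else "",
                         paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(path, if (nzchar(path)) "." else "", nm))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' @rdname pipeline_config
#' @param path A YAML file with (a subset of) the configuration sections.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("config file `%s` does not exist.", path))
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config An `ags_pipeline_config` to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "ags_pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
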