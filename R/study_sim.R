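#' Training-study schedule
#'
#' The multi-week protocol template: every patient trains at least weekly
#' over the study period; each training session opens with a warm-up at the
#' therapist's constant guidance force, followed by the adaptive exercise
#' (one block per leg), followed by conventional constant-guidance training.
#' Three assessment sessions (walking tests, isometric force) fall in fixed
#' weeks.
#'
#' @param weeks Study length in weeks (default 8).
#' @param min_sessions Minimum adaptive training sessions per patient
#'   (default 8; fewer triggers a warning downstream, not an error).
#' @param extra_session_prob Probability a patient trains more than the
#'   minimum.
#' @param extra_session_max Maximum number of extra sessions.
#' @param warmup_min,adaptive_min,conventional_min Block durations in
#'   minutes; the adaptive exercise runs `adaptive_min` per leg (left first).
#' @param assessment_weeks Weeks of the three assessment sessions.
#' @param guidance_margin Safety margin the simulated therapist adds above
#'   the patient's weakest-window stiffness requirement when choosing the
#'   conventional guidance force.
#' @param guidance_drift_sd Session-to-session SD of the guidance force.
#' @param simulate_conventional Simulate warm-up and conventional blocks in
#'   full (needed to render complete session logs). When `FALSE` only the
#'   guidance force is recorded, which is all the analyses use.
#' @return A list of class `ags_schedule`.
#' @export
study_schedule <- function(weeks = 8, min_sessions = 8,
                           extra_session_prob = 0.4, extra_session_max = 8,
                           warmup_min = 2, adaptive_min = 5,
                           conventional_min = 15,
                           assessment_weeks = c(1, 5, 8),
                           guidance_margin = 0.15,
                           guidance_drift_sd = 0.02,
                           simulate_conventional = TRUE) {
  check_scalar_positive(weeks, "weeks")
  check_scalar_positive(min_sessions, "min_sessions")
  check_scalar_positive(adaptive_min, "adaptive_min")
  if (length(assessment_weeks) < 1L || any(assessment_weeks > weeks)) {
    stop_invalid("`assessment_weeks` must fall within the study period.")
  }
  structure(as.list(environment()), class = "ags_schedule")
}

#' Simulate a complete training study
#'
#' Runs the whole protocol for every patient of a cohort: per-patient
#' session counts and dates, a therapist guidance force anchored just above
#' the patient's weakest-window requirement, warm-up / adaptive-left /
#' adaptive-right / conventional blocks per session (adaptive always first
#' after warm-up), session-to-session impairment variability and a slow
#' per-patient improvement trend, and clinical assessment records attached
#' to the training sessions nearest the assessment weeks. The walking
#' outcomes of each assessment are coupled to the patient's *current*
#' simulated knee initial-swing stiffness plateau.
#'
#' @param cohort An `ags_cohort` from [sample_cohort()].
#' @param schedule A [study_schedule()].
#' @param config A [controller_config()].
#' @param reference A [gait_reference()].
#' @param clinical An [clinical_params()].
#' @param seed Optional seed: the complete study is reproducible given it.
#' @param keep_deviation Keep per-cycle deviation arrays (needed to render
#'   session logs to CSV; off by default to save memory).
#' @return An object of class `ags_study`: a list with the cohort, a
#'   `sessions` tibble (one row per training session with the session
#'   objects in a list-column), a `clinical` tibble of assessment records,
#'   and the generating configuration.
#' @examples
#' study <- simulate_study(sample_cohort(2, seed = 1), seed = 2,
#'                         schedule = study_schedule(simulate_conventional = FALSE))
#' study$sessions[c("patient_id", "session_index", "day", "guidance_force")]
#' @export
simulate_study <- function(cohort, schedule = study_schedule(),
                           config = controller_config(),
                           reference = gait_reference(),
                           clinical = clinical_params(),
                           seed = NULL, keep_deviation = FALSE) {
  stopifnot(inherits(cohort, "ags_cohort"), inherits(schedule, "ags_schedule"))
  validate_controller_config(config)
  if (schedule$min_sessions < 8) {
    warn("fewer than 8 training sessions per patient scheduled.")
  }
  set_seed_if(seed)

  session_rows <- list()
  clinical_rows <- list()
  grid <- window_grid(dim(cohort$profile[[1L]]$c)[3L])
  map <- subphase_map()

  for (pi in seq_len(nrow(cohort))) {
    patient <- cohort$profile[[pi]]
    n_extra <- if (runif(1) < schedule$extra_session_prob) {
      sample.int(schedule$extra_session_max, 1L)
    } else 0L
    n_sessions <- as.integer(schedule$min_sessions + n_extra)
    days <- sort(sample.int(schedule$weeks * 7L - 2L, n_sessions) + 1L)

    g_req <- max(fixed_point_stiffness(patient$c, config))
    g_base <- min(1, g_req + schedule$guidance_margin)

    # map each assessment week to the nearest training session
    target_days <- (schedule$assessment_weeks - 0.5) * 7
    assess_session <- vapply(target_days, function(d) which.min(abs(days - d)),
                             integer(1))

    for (si in seq_len(n_sessions)) {
      improvement <- max(0.2, 1 - patient$improvement_rate * (si - 1L))
      m <- max(0, 1 + rnorm(1, 0, patient$session_variability)) * improvement
      guidance <- clamp(g_base + rnorm(1, 0, schedule$guidance_drift_sd),
                        min(1, g_req + schedule$guidance_margin / 2), 1)

      blocks <- list()
      if (schedule$simulate_conventional) {
        blocks$warmup <- run_conventional_block(
          patient, reference, guidance, schedule$warmup_min,
          grid = grid, map = map, impairment_scale = m,
          phase = "warmup", keep_deviation = keep_deviation
        )
      }
      blocks$adaptive_left <- run_adaptive_block(
        patient, reference, config, schedule$adaptive_min, "left",
        grid = grid, map = map, impairment_scale = m,
        keep_deviation = keep_deviation
      )
      blocks$adaptive_right <- run_adaptive_block(
        patient, reference, config, schedule$adaptive_min, "right",
        grid = grid, map = map, impairment_scale = m,
        keep_deviation = keep_deviation
      )
      if (schedule$simulate_conventional) {
        blocks$conventional <- run_conventional_block(
          patient, reference, guidance, schedule$conventional_min,
          grid = grid, map = map, impairment_scale = m,
          phase = "conventional", keep_deviation = keep_deviation
        )
      }

      k_is <- session_knee_is_plateau(blocks, grid, map)
      sess <- structure(
        list(patient_id = patient$patient_id, session_index = si,
             day = days[si], guidance_force = guidance,
             impairment_scale = m, k_knee_is = k_is, blocks = blocks),
        class = "ags_training_session"
      )
      ai <- match(si, assess_session)
      session_rows[[length(session_rows) + 1L]] <- tibble(
        patient_id = patient$patient_id, session_index = si,
        day = days[si], week = ceiling(days[si] / 7),
        guidance_force = guidance, k_knee_is = k_is,
        assessment_index = if (is.na(ai)) NA_integer_ else as.integer(ai),
        session = list(sess)
      )
      if (!is.na(ai)) {
        rec <- simulate_clinical_tests(patient, ai, k_knee_is = 100 * k_is,
                                       params = clinical)
        rec$session_index <- si
        rec$day <- days[si]
        clinical_rows[[length(clinical_rows) + 1L]] <- rec
      }
    }
  }

  structure(
    list(
      cohort = cohort,
      sessions = bind_rows(session_rows),
      clinical = bind_rows(clinical_rows),
      schedule = schedule, config = config, reference = reference,
      clinical_params = clinical, seed = seed
    ),
    class = "ags_study"
  )
}

# Generation-side knee initial-swing plateau of one session: mean over both
# legs of the last-4-minute mean of the per-cycle knee stiffness in the IS
# windows (fractions, not percent).
session_knee_is_plateau <- function(blocks, grid, map) {
  wins <- which(window_subphases(grid, map) == "IS")
  per_leg <- vapply(c("adaptive_left", "adaptive_right"), function(nm) {
    blk <- blocks[[nm]]
    last_cycles <- which((seq_len(blk$n_cycles) - 1) / blk$cadence >=
                           blk$duration_min - 4)
    mean(blk$k[2L, wins, last_cycles])
  }, numeric(1))
  mean(per_leg)
}

#' @export
print.ags_study <- function(x, ...) {
  cat(sprintf(
    "<ags_study> %d patients | %d training sessions | %d assessment records\n",
    nrow(x$cohort), nrow(x$sessions), nrow(x$clinical)
  ))
  invisible(x)
}

#' Per-session subphase features for a whole study
#'
#' Applies [extract_session_features()] to every (or every
#' assessment-linked) training session of a simulated study.
#'
#' @param study An `ags_study`.
#' @param sessions `"all"` or `"assessment"` (only sessions an assessment is
#'   attached to).
#' @param config An [feature_config()].
#' @return A tibble with one row per session, leg and feature: columns
#'   `patient_id`, `session_index`, `day`, `assessment_index`, `leg`,
#'   `quantity`, `joint`, `subphase`, `value`, `method`.
#' @export
extract_study_features <- function(study, sessions = c("all", "assessment"),
                                   config = feature_config()) {
  stopifnot(inherits(study, "ags_study"))
  sessions <- match.arg(sessions)
  rows <- study$sessions
  if (sessions == "assessment") rows <- rows[!is.na(rows$assessment_index), ]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    feats <- extract_session_features(rows$session[[i]], config)
    feats$patient_id <- rows$patient_id[i]
    feats$session_index <- rows$session_index[i]
    feats$day <- rows$day[i]
    feats$assessment_index <- rows$assessment_index[i]
    feats
  })
  out <- bind_rows(out)
  select(out, all_of(c("patient_id", "session_index", "day", "assessment_index",
                       "leg", "quantity", "joint", "subphase", "value", "method")))
}

#' Per-patient robotic support levels: adaptive versus conventional
#'
#' For every patient, the mean normalized stiffness reached during adaptive
#' training (averaged over hip and knee, both legs, all windows and all
#' post-transient cycles of every session) and the mean conventional
#' guidance force the simulated therapist selected.
#'
#' @param study An `ags_study`.
#' @param exclusion_min Minutes excluded from the start of each adaptive
#'   block (default 1).
#' @return A tibble with columns `patient_id`, `ags_mean`,
#'   `conventional_mean` (fractions of full support).
#' @export
support_levels <- function(study, exclusion_min = 1) {
  stopifnot(inherits(study, "ags_study"))
  rows <- study$sessions
  per_session <- vapply(rows$session, function(sess) {
    vals <- vapply(c("adaptive_left", "adaptive_right"), function(nm) {
      blk <- sess$blocks[[nm]]
      keep <- (seq_len(blk$n_cycles) - 1) / blk$cadence >= exclusion_min
      mean(blk$k[, , keep])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  tibble(patient_id = rows$patient_id, ags = per_session,
         guidance = rows$guidance_force) %>%
    group_by(.data$patient_id) %>%
    summarise(ags_mean = mean(.data$ags),
              conventional_mean = mean(.data$guidance), .groups = "drop")
}
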