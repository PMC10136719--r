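ags_variables <- as.vector(outer(
  c("k", "b"),
  as.vector(outer(c("knee", "hip"), c("is", "ms", "ts"), paste, sep = "_")),
  paste, sep = "_"
))

#' Assemble the per-patient clinical feature table
#'
#' Joins the walking, isometric-force and adaptive-training data at the
#' patient level, the way the cross-sectional validity analyses consume
#' them: 10-meter-walk run times are averaged within each assessment and
#' converted to speed (10 m divided by the mean run time), timed-up-and-go
#' runs are averaged, isometric torques are normalized to body weight and
#' averaged over the four movements per leg, the 12 adaptive-training
#' variables are leg-averaged per assessment session and expressed in
#' percent, and everything is then averaged over the (three) assessments.
#' Non-ambulatory patients carry `NA` walking outcomes and are excluded from
#' walking-validity models downstream.
#'
#' @param study An `ags_study`.
#' @param features A per-session feature table from
#'   [extract_study_features()] that covers the assessment-linked sessions.
#' @return An `ags_clinical_table` tibble: one row per patient with columns
#'   `patient_id`, `ambulatory`, `n_assessments`, `speed_10mwt`, `tug_s`,
#'   `lforce_left`, `lforce_right`, `lforce_mean`, the 12 variables
#'   `k_knee_is` ... `b_hip_ts` (percent), and per-leg `k_knee_is_left`,
#'   `k_knee_is_right` (percent).
#' @export
prepare_clinical_features <- function(study, features) {
  stopifnot(inherits(study, "ags_study"))
  if (nrow(study$clinical) == 0L) {
    stop_insufficient("study contains no assessment records.")
  }

  assess_feats <- features %>%
    filter(!is.na(.data$assessment_index)) %>%
    mutate(variable = paste(tolower(.data$quantity), .data$joint,
                            tolower(.data$subphase), sep = "_"))

  # leg-averaged 12 variables per assessment, then averaged over assessments
  vars_wide <- assess_feats %>%
    group_by(.data$patient_id, .data$assessment_index, .data$variable) %>%
    summarise(value = 100 * mean(.data$value), .groups = "drop") %>%
    group_by(.data$patient_id, .data$variable) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "variable", values_from = "value")

  knee_is_legs <- assess_feats %>%
    filter(.data$variable == "k_knee_is") %>%
    group_by(.data$patient_id, .data$leg) %>%
    summarise(value = 100 * mean(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "leg", values_from = "value",
                       names_prefix = "k_knee_is_")

  lforce_cols <- function(leg) paste0("lforce_", leg, "_", lforce_movements)
  clin <- study$clinical %>%
    mutate(
      mean_run_s = (.data$tenmwt_run1_s + .data$tenmwt_run2_s) / 2,
      speed = 10 / .data$mean_run_s,
      tug = (.data$tug_run1_s + .data$tug_run2_s) / 2,
      lforce_left = rowMeans(across(all_of(lforce_cols("left")))) / .data$body_weight,
      lforce_right = rowMeans(across(all_of(lforce_cols("right")))) / .data$body_weight
    ) %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_assessments = dplyr::n(),
      speed_10mwt = mean(.data$speed),
      tug_s = mean(.data$tug),
      lforce_left = mean(.data$lforce_left),
      lforce_right = mean(.data$lforce_right),
      .groups = "drop"
    ) %>%
    mutate(lforce_mean = (.data$lforce_left + .data$lforce_right) / 2)

  missing <- setdiff(study$cohort$patient_id, clin$patient_id)
  if (length(missing) > 0L) {
    warn(sprintf("patient(s) %s have no assessments and were excluded.",
                 paste(missing, collapse = ", ")))
  }

  out <- study$cohort %>%
    select(all_of(c("patient_id", "ambulatory"))) %>%
    dplyr::inner_join(clin, by = "patient_id") %>%
    left_join(vars_wide, by = "patient_id") %>%
    left_join(knee_is_legs, by = "patient_id")
  class(out) <- unique(c("ags_clinical_table", class(out)))
  out
}

#' First-to-last session change
#'
#' Change of a per-session variable from the first to the last training
#' session, in the variable's own units (percentage points when the input is
#' the leg-averaged normalized stiffness in percent).
#'
#' @param values Per-session values.
#' @param sessions Optional session order; defaults to the given order.
#' @return `last - first`, a single number.
#' @examples
#' percent_change_first_last(c(20.0, 18.1, 16.6)) # -3.4
#' @export
percent_change_first_last <- function(values, sessions = NULL) {
  if (length(values) < 2L) {
    stop_insufficient("at least two sessions are needed for a change score.")
  }
  if (!is.null(sessions)) values <- values[order(sessions)]
  unname(values[length(values)] - values[1L])
}

#' Per-patient first-to-last change in knee initial-swing stiffness
#'
#' @param features A per-session feature table from
#'   [extract_study_features()] covering all sessions.
#' @return A tibble with columns `patient_id`, `first_pct`, `last_pct`,
#'   `change_pct` (leg-averaged knee IS stiffness, percentage points).
#' @export
stiffness_change_table <- function(features) {
  features %>%
    filter(.data$quantity == "K", .data$joint == "knee", .data$subphase == "IS") %>%
    group_by(.data$patient_id, .data$session_index) %>%
    summarise(value = 100 * mean(.data$value), .groups = "drop") %>%
    arrange(.data$patient_id, .data$session_index) %>%
    group_by(.data$patient_id) %>%
    summarise(
      first_pct = first(.data$value),
      last_pct = last(.data$value),
      change_pct = percent_change_first_last(.data$value, .data$session_index),
      .groups = "drop"
    )
}
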