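#' Cohort generator parameters
#'
#' Tuning constants of the synthetic rehabilitation cohort. A latent ability
#' score in `[0, 1]` drives both the tracking impairment (deviation magnitude
#' at zero support, degrees) and the isometric force capacity, each with
#' independent noise so the force-versus-control subgroups seen in clinical
#' cohorts (weak with poor control, weak with regained control, strong with
#' good control) are all populated.
#'
#' Impairment per joint, leg and window is
#' `c = c_max * (1 - ability) * weight(subphase) * joint_factor * jitter * asymmetry`,
#' with initial swing the hardest subphase. The knee initial-swing variable
#' is jitter-free: it defines the severity axis, and `c_max = 13` degrees
#' places ambulatory knee initial-swing plateaus in the roughly 4-35% range
#' over which the linearly coupled walking outcomes stay physiological.
#'
#' @param c_max Maximum impairment magnitude in degrees at ability 0.
#' @param subphase_weights Named difficulty weights for stance/IS/MS/TS.
#' @param hip_factor Hip impairment relative to knee.
#' @param var_jitter_sd Log-SD of the independent per-(joint, subphase)
#'   impairment jitter.
#' @param session_variability SD of the multiplicative session-to-session
#'   impairment change (drawn once per session).
#' @param cycle_variability SD of the multiplicative cycle-to-cycle tracking
#'   noise within a session.
#' @param leg_asym_sd Log-SD of the right/left impairment asymmetry ratio.
#'   Asymmetry redistributes impairment between the legs (one leg scaled by
#'   `sqrt(ratio)`, the other by its inverse) without changing the
#'   patient's overall severity.
#' @param amb_knee_is_cap Upper bound (degrees) on the knee initial-swing
#'   impairment of ambulatory patients: walking requires foot clearance, so
#'   an ambulatory patient's initial-swing deficit is bounded by
#'   definition.
#' @param vel_factor Mean ratio of velocity to position deviation (1/s).
#' @param vel_jitter_sd Log-SD of the per-(joint, subphase) velocity jitter.
#' @param force_max Force capacity in Nm/kg at ability 1.
#' @param force_noise_sd SD of additive force-capacity noise (Nm/kg).
#' @param ambulatory_threshold Ability above which a patient is ambulatory.
#' @param regained_control_prob Probability that a non-ambulatory patient has
#'   partially regained motor control (impairment scaled down) despite
#'   persistent weakness.
#' @param regained_control_factor Impairment multiplier for that subtype.
#' @param improvement_mean,improvement_sd Per-session proportional change in
#'   impairment over the training course (positive = improvement).
#' @param body_weight_mean,body_weight_sd Body weight distribution (kg).
#'
#' @return A list of class `ags_cohort_params`.
#' @export
cohort_params <- function(c_max = 13,
                          subphase_weights = c(stance = 0.3, IS = 1, MS = 0.45, TS = 0.55),
                          hip_factor = 0.5,
                          var_jitter_sd = 0.25,
                          session_variability = 0.08,
                          cycle_variability = 0.04,
                          leg_asym_sd = 0.1,
                          amb_knee_is_cap = 6.5,
                          vel_factor = 5,
                          vel_jitter_sd = 0.2,
                          force_max = 0.85,
                          force_noise_sd = 0.03,
                          ambulatory_threshold = 0.45,
                          regained_control_prob = 0.2,
                          regained_control_factor = 0.25,
                          improvement_mean = 0.01,
                          improvement_sd = 0.015,
                          body_weight_mean = 75,
                          body_weight_sd = 12) {
  if (!all(c("stance", "IS", "MS", "TS") %in% names(subphase_weights))) {
    stop_invalid("`subphase_weights` must name stance, IS, MS and TS.")
  }
  structure(as.list(environment()), class = "ags_cohort_params")
}

#' Construct a single synthetic patient profile
#'
#' Builds an `ags_patient` with a uniform impairment magnitude across joints,
#' legs and windows: the deterministic building block behind the closed-form
#' and fixed-point oracles. `c_deg = 0` gives an able-bodied (zero tracking
#' error) profile. Cohorts with realistic heterogeneity come from
#' [sample_cohort()].
#'
#' @param c_deg Mean absolute deviation in degrees at zero support, recycled
#'   over joints, legs and windows.
#' @param session_variability SD of the multiplicative deviation noise
#'   (0 = deterministic).
#' @param cycle_variability SD of the cycle-to-cycle tracking noise within a
#'   block; defaults to `session_variability` so a single argument controls
#'   both for this uniform profile.
#' @param vel_factor Velocity-to-position deviation ratio (1/s).
#' @param patient_id,ambulatory,fac,body_weight,force_capacity Descriptors.
#' @param grid A [window_grid()] fixing the number of windows.
#' @return An object of class `ags_patient`.
#' @examples
#' patient_profile(0)      # able-bodied
#' patient_profile(20)     # constant-deviation impaired model
#' @export
patient_profile <- function(c_deg = 0, session_variability = 0,
                            cycle_variability = session_variability,
                            vel_factor = 5,
                            patient_id = 0L, ambulatory = TRUE, fac = 5L,
                            body_weight = 75, force_capacity = c(left = 0.5, right = 0.5),
                            grid = window_grid()) {
  if (any(c_deg < 0)) stop_invalid("`c_deg` must be non-negative.")
  if (session_variability < 0) stop_invalid("`session_variability` must be >= 0.")
  if (cycle_variability < 0) stop_invalid("`cycle_variability` must be >= 0.")
  nw <- grid$n_windows
  dn <- list(joint = c("hip", "knee"), leg = c("left", "right"),
             window = as.character(seq_len(nw) - 1L))
  new_patient(
    patient_id = as.integer(patient_id),
    ability = NA_real_,
    ambulatory = isTRUE(ambulatory),
    fac = as.integer(fac),
    body_weight = body_weight,
    force_capacity = rep_len(force_capacity, 2L),
    session_variability = session_variability,
    cycle_variability = cycle_variability,
    leg_asymmetry = 1,
    regained_control = FALSE,
    improvement_rate = 0,
    c = array(rep_len(c_deg, 4L * nw), dim = c(2L, 2L, nw), dimnames = dn),
    vel_factor = array(vel_factor, dim = c(2L, 2L, nw), dimnames = dn)
  )
}

new_patient <- function(...) {
  p <- list(...)
  names(p$force_capacity) <- c("left", "right")
  structure(p, class = "ags_patient")
}

#' @export
print.ags_patient <- function(x, ...) {
  cat(sprintf(
    "<ags_patient> id %d | %s (FAC %d) | max impairment %.1f deg | force %.2f/%.2f Nm/kg\n",
    x$patient_id, if (x$ambulatory) "ambulatory" else "non-ambulatory",
    x$fac, max(x$c), x$force_capacity[["left"]], x$force_capacity[["right"]]
  ))
  invisible(x)
}

#' Sample a synthetic patient cohort
#'
#' Draws `n` heterogeneous patients. Ability scores are uniform on
#' `(0.05, 0.95)`; patients above the ambulatory threshold (0.45) can perform
#' overground walking tests, the rest cannot (their walking outcomes are
#' absent by construction). See [cohort_params()] for how ability maps to
#' impairment and force capacity.
#'
#' @param n Number of patients (>= 1).
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @param params An [cohort_params()].
#' @param grid A [window_grid()].
#' @param map A [subphase_map()].
#' @return An `ags_cohort`: a tibble with one row per patient, descriptor
#'   columns, and a `profile` list-column of `ags_patient` objects.
#' @examples
#' sample_cohort(3, seed = 1)
#' @export
sample_cohort <- function(n = 10, seed = NULL, params = cohort_params(),
                          grid = window_grid(), map = subphase_map()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop_invalid("`n` must be a positive whole number.")
  }
  stopifnot(inherits(params, "ags_cohort_params"))
  set_seed_if(seed)
  win_phase <- as.character(window_subphases(grid, map))
  profiles <- lapply(seq_len(n), function(i) {
    sample_patient(i, params, grid, win_phase)
  })
  out <- tibble(
    patient_id = vapply(profiles, `[[`, integer(1), "patient_id"),
    ability = vapply(profiles, `[[`, numeric(1), "ability"),
    ambulatory = vapply(profiles, `[[`, logical(1), "ambulatory"),
    fac = vapply(profiles, `[[`, integer(1), "fac"),
    body_weight = vapply(profiles, `[[`, numeric(1), "body_weight"),
    force_left = vapply(profiles, function(p) p$force_capacity[["left"]], numeric(1)),
    force_right = vapply(profiles, function(p) p$force_capacity[["right"]], numeric(1)),
    profile = profiles
  )
  class(out) <- c("ags_cohort", class(out))
  out
}

sample_patient <- function(i, params, grid, win_phase) {
  nw <- grid$n_windows
  ability <- runif(1, 0.05, 0.95)
  ambulatory <- ability > params$ambulatory_threshold
  regained <- !ambulatory && runif(1) < params$regained_control_prob

  # FAC 0-5: non-ambulatory patients sit at 0-2, ambulatory at 3-5
  fac <- if (ambulatory) {
    3L + as.integer(round(2 * (ability - params$ambulatory_threshold) /
                            (0.95 - params$ambulatory_threshold)))
  } else {
    as.integer(round(2 * (ability - 0.05) / (params$ambulatory_threshold - 0.05)))
  }

  body_weight <- clamp(rnorm(1, params$body_weight_mean, params$body_weight_sd), 45, 110)
  force <- clamp(params$force_max * ability + rnorm(2, 0, params$force_noise_sd),
                 0.02, 1.5)
  asym <- exp(rnorm(1, 0, params$leg_asym_sd))

  # independent jitter per (joint, subphase) decorrelates the 12 analysis
  # variables from the shared ability score; the knee initial-swing
  # impairment carries no jitter because it *defines* the severity axis the
  # walking outcomes are coupled to
  phases <- c("stance", "IS", "MS", "TS")
  jit_c <- matrix(exp(rnorm(8, 0, params$var_jitter_sd)), 2, 4,
                  dimnames = list(c("hip", "knee"), phases))
  jit_c["knee", "IS"] <- 1
  jit_v <- matrix(exp(rnorm(8, 0, params$vel_jitter_sd)), 2, 4,
                  dimnames = list(c("hip", "knee"), phases))

  base <- params$c_max * (1 - ability) *
    (if (regained) params$regained_control_factor else 1)
  dn <- list(joint = c("hip", "knee"), leg = c("left", "right"),
             window = as.character(seq_len(nw) - 1L))
  c_arr <- array(0, dim = c(2L, 2L, nw), dimnames = dn)
  v_arr <- array(params$vel_factor, dim = c(2L, 2L, nw), dimnames = dn)
  for (j in 1:2) {
    jf <- if (j == 1) params$hip_factor else 1
    cw <- base * jf * params$subphase_weights[win_phase] * jit_c[j, win_phase]
    if (j == 2L && ambulatory) {
      # ambulatory patients achieve foot clearance: their knee
      # initial-swing deficit is bounded
      is_win <- win_phase == "IS"
      cw[is_win] <- pmin(cw[is_win], params$amb_knee_is_cap)
    }
    c_arr[j, 1, ] <- cw / sqrt(asym)
    c_arr[j, 2, ] <- cw * sqrt(asym)
    v_arr[j, , ] <- rep(params$vel_factor * jit_v[j, win_phase], each = 2)
  }

  new_patient(
    patient_id = as.integer(i),
    ability = ability,
    ambulatory = ambulatory,
    fac = clamp(fac, 0L, 5L),
    body_weight = body_weight,
    force_capacity = force,
    session_variability = params$session_variability,
    cycle_variability = params$cycle_variability,
    leg_asymmetry = asym,
    regained_control = regained,
    improvement_rate = rnorm(1, params$improvement_mean, params$improvement_sd),
    c = c_arr,
    vel_factor = v_arr
  )
}

#' Extract one patient's profile from a cohort
#'
#' @param cohort An `ags_cohort` from [sample_cohort()].
#' @param patient_id Patient identifier.
#' @return The `ags_patient` object.
#' @export
cohort_patient <- function(cohort, patient_id) {
  idx <- match(patient_id, cohort$patient_id)
  if (is.na(idx)) stop_invalid(sprintf("no patient with id %s.", patient_id))
  cohort$profile[[idx]]
}

#' Simulated tracking deviation under partial support
#'
#' The synthetic patient model: the mean absolute deviation from the
#' reference in a window is `c * (1 - K) * (1 + eta)` with
#' `eta ~ Normal(0, session_variability)`, truncated at zero. Full support
#' (`K = 1`) or an able-bodied profile (`c = 0`) produces zero deviation.
#'
#' @param patient An `ags_patient`.
#' @param joint `"hip"` or `"knee"`.
#' @param leg `"left"` or `"right"`.
#' @param window Window index (or indices) in `[0, n_windows)`.
#' @param k Normalized stiffness in `[0, 1]`, recycled against `window`.
#' @param seed Optional seed for the noise draw.
#' @return Deviation(s) in degrees, same length as `window`.
#' @examples
#' simulate_tracking_error(patient_profile(20), "knee", "left", 0, k = 0.5)
#' @export
simulate_tracking_error <- function(patient, joint = c("hip", "knee"),
                                    leg = c("left", "right"), window, k,
                                    seed = NULL) {
  stopifnot(inherits(patient, "ags_patient"))
  joint <- match.arg(joint)
  leg <- match.arg(leg)
  if (any(k < 0 | k > 1)) stop_invalid("`k` must lie in [0, 1].")
  set_seed_if(seed)
  cvec <- patient$c[joint, leg, window + 1L]
  sd <- patient$session_variability
  eta <- if (sd > 0) rnorm(length(cvec), 0, sd) else 0
  pmax(0, cvec * (1 - k) * (1 + eta))
}

#' Clinical outcome generator parameters
#'
#' Ground-truth coupling of the simulated walking tests to the knee
#' stiffness plateau at initial swing (`k`, in percent): walking speed
#' `= beta0 + slope_speed * k + noise` (floored at `speed_floor`) and
#' timed-up-and-go time `= alpha0 + slope_tug * k + noise`. The slopes
#' default to -0.04 m/s and +3.38 s per percentage point.
#'
#' @param beta0 Intercept walking speed, m/s.
#' @param slope_speed Speed change per percent knee-IS stiffness (m/s).
#' @param sigma_speed SD of the speed noise (m/s).
#' @param speed_floor Minimum attainable speed (m/s).
#' @param alpha0 Intercept TUG time, s.
#' @param slope_tug TUG change per percent knee-IS stiffness (s).
#' @param sigma_tug SD of the TUG noise (s).
#' @param run_jitter_sd Relative SD of run-to-run timing jitter.
#' @param lforce_jitter_sd Relative SD of per-movement torque jitter.
#' @return A list of class `ags_clinical_params`.
#' @export
clinical_params <- function(beta0 = 1.9, slope_speed = -0.04,
                            sigma_speed = 0.15, speed_floor = 0.05,
                            alpha0 = 12, slope_tug = 3.38, sigma_tug = 10,
                            run_jitter_sd = 0.02, lforce_jitter_sd = 0.05) {
  structure(as.list(environment()), class = "ags_clinical_params")
}

lforce_movements <- c("hip_flex", "hip_ext", "knee_flex", "knee_ext")

#' Simulate one assessment session's clinical tests
#'
#' Generates a clinical record for one assessment: two timed runs each of
#' the 10-meter walk test and the timed-up-and-go test (ambulatory patients
#' only; the fields are `NA` otherwise), raw isometric joint torques for the
#' four movements of both legs, and the body weight used for normalization.
#'
#' @param patient An `ags_patient`.
#' @param assessment_index Assessment number (1-3).
#' @param k_knee_is Current knee initial-swing stiffness plateau in percent,
#'   the regressor the walking outcomes are coupled to.
#' @param seed Optional seed.
#' @param params An [clinical_params()].
#' @return A one-row tibble with columns `patient_id`, `assessment_index`,
#'   `tenmwt_run1_s`, `tenmwt_run2_s`, `tug_run1_s`, `tug_run2_s`,
#'   `body_weight`, and `lforce_<leg>_<movement>` (Nm).
#' @examples
#' p <- patient_profile(5, force_capacity = c(0.4, 0.4))
#' simulate_clinical_tests(p, 1, k_knee_is = 5, seed = 1)
#' @export
simulate_clinical_tests <- function(patient, assessment_index, k_knee_is,
                                    seed = NULL, params = clinical_params()) {
  stopifnot(inherits(patient, "ags_patient"), inherits(params, "ags_clinical_params"))
  if (k_knee_is < 0) stop_invalid("`k_knee_is` must be non-negative (percent).")
  set_seed_if(seed)

  if (patient$ambulatory) {
    speed <- max(params$speed_floor,
                 params$beta0 + params$slope_speed * k_knee_is +
                   rnorm(1, 0, params$sigma_speed))
    base_run <- 10 / speed
    tenmwt <- base_run * (1 + rnorm(2, 0, params$run_jitter_sd))
    tug_base <- max(2, params$alpha0 + params$slope_tug * k_knee_is +
                      rnorm(1, 0, params$sigma_tug))
    tug <- tug_base * (1 + rnorm(2, 0, params$run_jitter_sd))
  } else {
    tenmwt <- c(NA_real_, NA_real_)
    tug <- c(NA_real_, NA_real_)
  }

  lf <- lapply(c("left", "right"), function(leg) {
    raw <- patient$force_capacity[[leg]] * patient$body_weight *
      (1 + rnorm(4, 0, params$lforce_jitter_sd))
    setNames(pmax(0, raw), paste0("lforce_", leg, "_", lforce_movements))
  })

  out <- tibble(
    patient_id = patient$patient_id,
    assessment_index = as.integer(assessment_index),
    tenmwt_run1_s = tenmwt[1], tenmwt_run2_s = tenmwt[2],
    tug_run1_s = tug[1], tug_run2_s = tug[2],
    body_weight = patient$body_weight
  )
  dplyr::bind_cols(out, as_tibble(as.list(c(lf[[1]], lf[[2]]))))
}
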