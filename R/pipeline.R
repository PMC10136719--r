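config_objects <- function(config) {
  g <- config$gait
  cp <- config$cohort
  cohort_args <- cp[setdiff(names(cp), c("n", "seed"))]
  cohort_args$subphase_weights <- unlist(cohort_args$subphase_weights)
  list(
    controller = do.call(controller_config, config$controller),
    reference = gait_reference(g$cadence, g$rom_hip, g$rom_knee,
                               g$offset_hip, g$offset_knee),
    grid = window_grid(g$n_windows),
    map = subphase_map(g$is_fraction, g$ms_fraction, g$ts_fraction),
    cohort_params = do.call(cohort_params, cohort_args),
    clinical = do.call(clinical_params, config$clinical),
    schedule = do.call(study_schedule, config$schedule),
    features = feature_config(config$analysis$exclusion_min,
                              config$analysis$last_minutes,
                              config$analysis$plateau_lambda_span,
                              config$analysis$plateau_rmse,
                              config$analysis$min_points)
  )
}

#' Simulation stage of the pipeline
#'
#' @param config An [pipeline_config()].
#' @param seed Seed override; defaults to `config$cohort$seed`.
#' @return An `ags_study`.
#' @export
pipeline_simulate <- function(config = pipeline_config(), seed = NULL) {
  stopifnot(inherits(config, "ags_pipeline_config"))
  obj <- config_objects(config)
  if (is.null(seed)) seed <- config$cohort$seed
  set_seed_if(seed)
  cohort <- sample_cohort(config$cohort$n, params = obj$cohort_params,
                          grid = obj$grid, map = obj$map)
  simulate_study(cohort, schedule = obj$schedule, config = obj$controller,
                 reference = obj$reference, clinical = obj$clinical)
}

#' Feature-extraction stage of the pipeline
#'
#' @param study An `ags_study`.
#' @param config An [pipeline_config()].
#' @return A per-session feature table (all sessions).
#' @export
pipeline_extract <- function(study, config = pipeline_config()) {
  extract_study_features(study, sessions = "all",
                         config = config_objects(config)$features)
}

#' Analysis stage of the pipeline
#'
#' Runs every study-level analysis on a simulated study and its extracted
#' features: the paired adaptive-versus-conventional support comparison,
#' forward and elastic-net variable selection for both walking outcomes
#' (skipped with a stated reason when too few patients completed the
#' walking tests), the first-to-last stiffness change table, test-retest
#' reliability of the knee initial-swing stiffness, the force-versus-control
#' clustering with per-leg regressions, and the cohort training summary.
#'
#' @param study An `ags_study`.
#' @param features A feature table from [pipeline_extract()].
#' @param config An [pipeline_config()].
#' @return A list of class `ags_analysis` with one element per analysis and
#'   a `skipped` list naming analyses that could not run and why.
#' @export
pipeline_analyze <- function(study, features, config = pipeline_config()) {
  an <- config$analysis
  skipped <- list()

  clinical <- prepare_clinical_features(study, features)
  support <- support_levels(study, exclusion_min = an$exclusion_min)
  paired <- NULL
  if (nrow(support) >= 3L) {
    paired <- compare_support_paired(support, ags_mean, conventional_mean)
  } else {
    skipped$paired <- sprintf(
      "support comparison skipped: only %d patient(s) (need >= 3 pairs).",
      nrow(support)
    )
  }

  walking <- clinical[stats::complete.cases(clinical[c("speed_10mwt", "k_knee_is")]), ]
  selection_10mwt <- selection_tug <- enet <- NULL
  if (nrow(walking) >= 4L) {
    selection_10mwt <- forward_select(walking, speed_10mwt,
                                      predictors = ags_variables,
                                      alpha_enter = an$alpha_enter)
    selection_tug <- forward_select(walking, tug_s,
                                    predictors = ags_variables,
                                    alpha_enter = an$alpha_enter)
    enet <- elastic_net_selection_frequency(
      walking, speed_10mwt, predictors = ags_variables,
      runs = an$enet_runs, alpha = an$enet_alpha, nfolds = an$enet_folds
    )
  } else {
    skipped$validity <- sprintf(
      "variable selection skipped: only %d patient(s) with complete walking data (need >= 4).",
      nrow(walking)
    )
  }

  change <- stiffness_change_table(features)

  per_session_kis <- features %>%
    filter(.data$quantity == "K", .data$joint == "knee", .data$subphase == "IS") %>%
    group_by(.data$patient_id, .data$session_index, .data$day) %>%
    summarise(value = 100 * mean(.data$value), .groups = "drop")
  pairs <- reliability_session_pair(per_session_kis, day, value)
  reliability <- NULL
  if (nrow(pairs) >= 3L) {
    reliability <- list(
      rho = spearman_relative_reliability(pairs$value_a, pairs$value_b),
      bland_altman = bland_altman_loa(pairs$value_a, pairs$value_b),
      pairs = pairs
    )
  } else {
    skipped$reliability <- sprintf(
      "reliability skipped: only %d patient(s) with a session pair (need >= 3).",
      nrow(pairs)
    )
  }

  clusters <- cluster_force_vs_control(
    clinical, lforce_mean, k_knee_is,
    force_threshold = an$force_threshold,
    stiffness_threshold = an$stiffness_threshold
  )

  structure(
    list(
      clinical = clinical, support = support, paired = paired,
      selection_10mwt = selection_10mwt, selection_tug = selection_tug,
      enet_frequency = enet, change = change, reliability = reliability,
      clusters = clusters, lforce_regression = lforce_ags_regression(clinical),
      cohort_summary = cohort_summary(study), skipped = skipped,
      config = config
    ),
    class = "ags_analysis"
  )
}

#' Run the full pipeline and write a report directory
#'
#' Simulates a study, extracts per-session features, runs all analyses and
#' writes the results as CSV tables plus a plain-text summary whose header
#' echoes the seed and analysis thresholds for reproducibility. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Report directory (created if needed).
#' @param seed Seed override; defaults to `config$cohort$seed`.
#' @return The `ags_analysis` list, invisibly, with the study and features
#'   attached as attributes.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "ags_pipeline_config"))
  if (is.null(seed)) seed <- config$cohort$seed
  study <- with_stage("simulate", pipeline_simulate(config, seed))
  features <- with_stage("extract", pipeline_extract(study, config))
  analysis <- with_stage("analyze", pipeline_analyze(study, features, config))
  with_stage("report", write_report(analysis, features, out_dir, seed))
  attr(analysis, "study") <- study
  attr(analysis, "features") <- features
  invisible(analysis)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
          class = "adaptgait_error_pipeline", parent = e)
  })
}

write_report <- function(analysis, features, out_dir, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }

  feats_out <- mutate(features, value_pct = 100 * .data$value) %>%
    select(-all_of("value"))
  wcsv(feats_out, "features.csv")
  wcsv(analysis$clinical, "clinical_features.csv")
  wcsv(analysis$support, "support_levels.csv")
  if (!is.null(analysis$paired)) {
    wcsv(tidy(analysis$paired), "support_comparison.csv")
  }
  if (!is.null(analysis$selection_10mwt)) {
    wcsv(tidy(analysis$selection_10mwt), "selection_10mwt.csv")
    wcsv(tidy(analysis$selection_tug), "selection_tug.csv")
    wcsv(analysis$enet_frequency, "enet_frequency.csv")
  }
  wcsv(analysis$change, "stiffness_change.csv")
  if (!is.null(analysis$reliability)) {
    rel <- analysis$reliability
    wcsv(tibble(
      rho = rel$rho, bias = rel$bland_altman$bias,
      loa_low = rel$bland_altman$loa_low, loa_high = rel$bland_altman$loa_high,
      loa_pct_of_mean = rel$bland_altman$loa_pct_of_mean, n = rel$bland_altman$n
    ), "reliability.csv")
  }
  wcsv(select(analysis$clusters,
              all_of(c("patient_id", "lforce_mean", "k_knee_is", "cluster"))),
       "clusters.csv")
  wcsv(analysis$lforce_regression, "lforce_regression.csv")
  cs <- analysis$cohort_summary
  wcsv(tibble(patient_id = names(cs$counts), n_sessions = as.integer(cs$counts)),
       "session_counts.csv")

  an <- analysis$config$analysis
  lines <- c(
    "adaptgait pipeline report",
    sprintf("seed: %s", seed),
    sprintf("thresholds: alpha_enter=%g, enet alpha=%g folds=%d runs=%d, force=%g Nm/kg, stiffness=%g%%",
            an$alpha_enter, an$enet_alpha, an$enet_folds, an$enet_runs,
            an$force_threshold, an$stiffness_threshold),
    sprintf("decay fit: exclusion %g min, fallback last %g min, plateau if rate*span >= %g and rmse <= %g",
            an$exclusion_min, an$last_minutes, an$plateau_lambda_span, an$plateau_rmse),
    "",
    sprintf("patients: %d | sessions: mean %.1f min %d max %d",
            length(cs$counts), cs$mean, as.integer(cs$min), as.integer(cs$max))
  )
  if (!is.null(analysis$paired)) {
    lines <- c(lines, sprintf(
      "paired support comparison: mean difference %.3f, p = %s",
      analysis$paired$estimate, format(analysis$paired$p_value, digits = 3)
    ))
  }
  if (!is.null(analysis$selection_10mwt)) {
    lines <- c(lines, sprintf(
      "10MWT forward selection: %s (R^2 = %.2f); TUG: %s (R^2 = %.2f)",
      paste(analysis$selection_10mwt$selected, collapse = " + "),
      analysis$selection_10mwt$r_squared,
      paste(analysis$selection_tug$selected, collapse = " + "),
      analysis$selection_tug$r_squared
    ))
  }
  if (!is.null(analysis$reliability)) {
    lines <- c(lines, sprintf(
      "reliability (knee IS stiffness): rho = %.2f, LOA half-width %.1f%% of mean",
      analysis$reliability$rho,
      analysis$reliability$bland_altman$loa_pct_of_mean
    ))
  }
  for (nm in names(analysis$skipped)) {
    lines <- c(lines, paste0("skipped: ", analysis$skipped[[nm]]))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
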