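#' Paired comparison of adaptive versus conventional support
#'
#' Two-sided paired t-test on the per-patient difference between the mean
#' support level reached by the adaptive controller and the conventional
#' guidance force set by the therapist, with a Shapiro-Wilk normality check
#' on the differences (reported, not gating). If all differences are
#' identical the variance is degenerate and no p-value is produced.
#'
#' @param data A data frame with one row per patient (e.g.
#'   [support_levels()] output).
#' @param ags,conventional Columns holding the paired support levels.
#' @return An object of class `ags_paired_test` with `tidy()` and
#'   `glance()` methods.
#' @examples
#' df <- tibble::tibble(a = c(0.2, 0.25, 0.3), c = c(0.6, 0.7, 0.65))
#' tidy(compare_support_paired(df, a, c))
#' @export
compare_support_paired <- function(data, ags, conventional) {
  a <- dplyr::pull(data, {{ ags }})
  b <- dplyr::pull(data, {{ conventional }})
  if (length(a) < 3L) stop_insufficient("need at least 3 paired observations.")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop_data("support levels must be finite.")
  d <- a - b
  degenerate <- isTRUE(all.equal(sd(d), 0)) || sd(d) == 0
  if (degenerate) {
    warn("all paired differences are identical; variance is degenerate and no p-value is reported.")
    res <- list(estimate = mean(d), statistic = NA_real_, df = NA_real_,
                p_value = NA_real_, shapiro_p = NA_real_,
                n = length(d), degenerate = TRUE)
  } else {
    tt <- t.test(a, b, paired = TRUE)
    sw <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
    res <- list(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                shapiro_p = sw, n = length(d), degenerate = FALSE)
  }
  structure(res, class = "ags_paired_test")
}

#' @export
print.ags_paired_test <- function(x, ...) {
  cat(sprintf(
    "<ags_paired_test> n = %d, mean difference = %.4f, t = %s, p = %s (Shapiro p = %s)\n",
    x$n, x$estimate, format(x$statistic, digits = 4),
    format(x$p_value, digits = 4), format(x$shapiro_p, digits = 3)
  ))
  invisible(x)
}

#' Forward stepwise variable selection by entry p-value
#'
#' Starting from the intercept-only model, repeatedly fits every
#' single-addition linear model and admits the candidate with the smallest
#' coefficient p-value, provided it is below `alpha_enter`; stops when no
#' candidate qualifies. No multiplicity correction is applied, so with many
#' pure-noise candidates the chance of at least one false entry is about
#' `1 - (1 - alpha)^p`. Candidates whose coefficient is inestimable
#' (collinear) are skipped with a warning.
#'
#' @param data A data frame; rows with missing values in the used columns
#'   are dropped.
#' @param response Response column (tidy-eval).
#' @param predictors Character vector of candidate columns; defaults to all
#'   numeric columns except the response.
#' @param alpha_enter Entry threshold (default 0.05).
#' @return An object of class `ags_selection`: fields `steps` (tibble of
#'   entered variables with entry p-values), `model` (the final `lm`),
#'   `selected`, `r_squared`, `n`; `tidy()` and `glance()` methods.
#' @export
forward_select <- function(data, response, predictors = NULL,
                           alpha_enter = 0.05) {
  resp <- as_name(enquo(response))
  if (is.null(predictors)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(numeric_cols, resp)
  }
  used <- data[, c(resp, predictors), drop = FALSE]
  used <- used[complete.cases(used), , drop = FALSE]
  n <- nrow(used)
  if (n < 3L) stop_insufficient("need at least 3 complete rows.")

  selected <- character(0)
  steps <- list()
  remaining <- predictors
  repeat {
    if (length(remaining) == 0L) break
    entry_p <- vapply(remaining, function(v) {
      fml <- stats::reformulate(c(selected, v), response = resp)
      fit <- lm(fml, data = used)
      cf <- summary(fit)$coefficients
      if (!(v %in% rownames(cf)) || is.na(coef(fit)[v])) {
        warn(sprintf("candidate `%s` is collinear with the current model; skipped.", v))
        return(NA_real_)
      }
      cf[v, "Pr(>|t|)"]
    }, numeric(1))
    if (all(is.na(entry_p))) break
    best <- which.min(entry_p)
    if (entry_p[best] >= alpha_enter) break
    selected <- c(selected, remaining[best])
    steps[[length(steps) + 1L]] <- tibble(
      step = length(selected), variable = remaining[best],
      p_entry = entry_p[best]
    )
    remaining <- remaining[-best]
  }

  fml <- stats::reformulate(if (length(selected)) selected else "1", response = resp)
  model <- lm(fml, data = used)
  steps_tbl <- if (length(steps) > 0L) {
    bind_rows(steps)
  } else {
    tibble(step = integer(), variable = character(), p_entry = numeric())
  }
  structure(
    list(
      steps = steps_tbl, model = model, selected = selected,
      response = resp, r_squared = summary(model)$r.squared, n = n,
      alpha_enter = alpha_enter
    ),
    class = "ags_selection"
  )
}

#' @export
print.ags_selection <- function(x, ...) {
  cat(sprintf("<ags_selection> %s ~ %s | R^2 = %.3f | n = %d\n",
              x$response,
              if (length(x$selected)) paste(x$selected, collapse = " + ") else "1",
              x$r_squared, x$n))
  invisible(x)
}

#' Elastic-net selection frequency over repeated cross-validations
#'
#' Fits a cross-validated elastic net (`glmnet`, L1 proportion `alpha`)
#' `runs` times with freshly randomized fold assignments, takes the
#' coefficients at the CV-minimum penalty each time, and reports for every
#' candidate the proportion of runs in which its coefficient was nonzero.
#' Repeating the fit exposes how stable the selection is under fold
#' resampling.
#'
#' @inheritParams forward_select
#' @param runs Number of repetitions (default 100).
#' @param alpha L1 proportion of the penalty (default 0.75).
#' @param nfolds Cross-validation folds (default 3).
#' @param seed Optional seed for the fold assignments.
#' @return A tibble with columns `variable`, `frequency`, carrying `runs`
#'   as an attribute.
#' @export
elastic_net_selection_frequency <- function(data, response, predictors = NULL,
                                            runs = 100, alpha = 0.75,
                                            nfolds = 3, seed = NULL) {
  resp <- as_name(enquo(response))
  if (is.null(predictors)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(numeric_cols, resp)
  }
  used <- data[, c(resp, predictors), drop = FALSE]
  used <- used[complete.cases(used), , drop = FALSE]
  n <- nrow(used)
  if (n < nfolds) stop_invalid("need at least as many rows as folds.")
  check_scalar_positive(runs, "runs")
  set_seed_if(seed)

  x <- as.matrix(used[, predictors, drop = FALSE])
  y <- used[[resp]]
  hits <- setNames(numeric(length(predictors)), predictors)
  constant <- apply(x, 2L, function(col) sd(col) < 1e-9 * (1 + abs(mean(col))))
  if (any(constant)) {
    warn(sprintf("constant candidate(s) excluded from the penalized fit: %s",
                 paste(predictors[constant], collapse = ", ")))
    x <- x[, !constant, drop = FALSE]
  }
  if (ncol(x) == 0L) {
    out <- tibble(variable = predictors, frequency = 0)
    attr(out, "runs") <- runs
    return(out)
  }
  for (r in seq_len(runs)) {
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                               grouped = FALSE)
    cf <- as.matrix(coef(cvfit, s = "lambda.min"))[-1L, 1L]
    hits[names(cf)] <- hits[names(cf)] + (abs(cf) > 0)
  }
  out <- tibble(variable = predictors, frequency = unname(hits) / runs)
  attr(out, "runs") <- runs
  out
}

#' Spearman rank correlation between two test occasions
#'
#' Relative (rank-order) test-retest reliability with average-rank tie
#' handling. A constant vector has no rank ordering and yields `NA` with a
#' warning.
#'
#' @param values_a,values_b Paired measurements (n >= 3).
#' @return Spearman's rho.
#' @examples
#' spearman_relative_reliability(1:4, c(1, 2, 4, 3)) # 0.8
#' @export
spearman_relative_reliability <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop_invalid("inputs must be paired.")
  if (length(values_a) < 3L) stop_insufficient("need at least 3 pairs.")
  if (sd(values_a) == 0 || sd(values_b) == 0) {
    warn("a constant vector has undefined rank correlation.")
    return(NA_real_)
  }
  cor(values_a, values_b, method = "spearman")
}

#' Bland-Altman 95% limits of agreement
#'
#' Absolute test-retest agreement: for paired measurements the bias is the
#' mean difference and the limits of agreement are
#' `bias +/- 1.96 * SD(differences)` (sample SD). The limits are also
#' expressed as a percentage of the mean of the data: the half-width
#' `1.96 * SD` divided by the grand mean of the pair averages (and, since
#' conventions differ, the full width as well).
#'
#' @param values_a,values_b Paired measurements (n >= 2).
#' @return An object of class `ags_bland_altman` with fields `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `half_width`, `loa_pct_of_mean`,
#'   `loa_pct_full_width`, `n`, and the paired data; `tidy()` and
#'   `autoplot()` methods.
#' @export
bland_altman_loa <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop_invalid("inputs must be paired.")
  if (length(values_a) < 2L) stop_insufficient("need at least 2 pairs.")
  d <- values_a - values_b
  m <- (values_a + values_b) / 2
  bias <- mean(d)
  sdd <- sd(d)
  half <- 1.96 * sdd
  grand <- mean(m)
  if (isTRUE(all.equal(grand, 0))) {
    warn("mean of the data is zero; percentage limits are undefined.")
    pct <- NA_real_
  } else {
    pct <- 100 * half / grand
  }
  structure(
    list(bias = bias, sd_diff = sdd, loa_low = bias - half,
         loa_high = bias + half, half_width = half,
         loa_pct_of_mean = pct, loa_pct_full_width = 2 * pct,
         n = length(d), means = m, diffs = d),
    class = "ags_bland_altman"
  )
}

#' @export
print.ags_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<ags_bland_altman> bias %.4f, LOA [%.4f, %.4f], half-width %.4f (%.1f%% of mean)\n",
    x$bias, x$loa_low, x$loa_high, x$half_width, x$loa_pct_of_mean
  ))
  invisible(x)
}

#' Pick the reliability session pair
#'
#' Selects, per patient, the two training sessions closest to each other in
#' time within the second half of the study period (ties go to the earlier
#' pair); test-retest reliability is computed on that pair.
#'
#' @param data A per-session table with one value per session (e.g. the
#'   leg-averaged knee IS stiffness).
#' @param day,value Columns giving session day and the variable under test.
#' @param midpoint Day separating the study halves; defaults to half the
#'   largest day observed.
#' @return A tibble with columns `patient_id`, `day_a`, `day_b`, `value_a`,
#'   `value_b`.
#' @export
reliability_session_pair <- function(data, day, value, midpoint = NULL) {
  day_v <- as_name(enquo(day))
  val_v <- as_name(enquo(value))
  if (is.null(midpoint)) midpoint <- max(data[[day_v]]) / 2
  data %>%
    group_by(.data$patient_id) %>%
    dplyr::group_modify(function(g, key) {
      g <- arrange(g, g[[day_v]])
      half <- g[g[[day_v]] > midpoint, , drop = FALSE]
      if (nrow(half) < 2L) {
        warn(sprintf("patient %s has fewer than 2 sessions after the midpoint; using the last two sessions.",
                     key$patient_id))
        half <- tail(g, 2L)
      }
      gaps <- diff(half[[day_v]])
      i <- which.min(gaps) # which.min takes the first (earliest) minimal gap
      tibble(day_a = half[[day_v]][i], day_b = half[[day_v]][i + 1L],
             value_a = half[[val_v]][i], value_b = half[[val_v]][i + 1L])
    }) %>%
    ungroup()
}

cluster_levels <- c("low-force/low-K", "low-force/high-K",
                    "high-force/low-K", "high-force/high-K")

#' Classify patients by isometric force versus required support
#'
#' Deterministic quadrant assignment of (mean normalized isometric force,
#' knee initial-swing stiffness) pairs by two thresholds; points on a
#' threshold go to the "high" side. The clinically expected occupied
#' quadrants are weak/high-support, weak/low-support (regained control with
#' persistent weakness) and strong/low-support; strong patients needing
#' high support are not expected.
#'
#' @param data A data frame (e.g. an `ags_clinical_table`).
#' @param force,stiffness Columns with the normalized force (Nm/kg) and the
#'   stiffness (percent).
#' @param force_threshold Force split in Nm/kg (default 0.4).
#' @param stiffness_threshold Stiffness split in percent (default 30).
#' @return `data` with an added `cluster` factor column.
#' @export
cluster_force_vs_control <- function(data, force, stiffness,
                                     force_threshold = 0.4,
                                     stiffness_threshold = 30) {
  check_scalar_positive(force_threshold, "force_threshold")
  check_scalar_positive(stiffness_threshold, "stiffness_threshold")
  f <- dplyr::pull(data, {{ force }})
  k <- dplyr::pull(data, {{ stiffness }})
  lab <- dplyr::case_when(
    f < force_threshold & k < stiffness_threshold ~ cluster_levels[1],
    f < force_threshold ~ cluster_levels[2],
    k < stiffness_threshold ~ cluster_levels[3],
    TRUE ~ cluster_levels[4]
  )
  mutate(data, cluster = factor(lab, levels = cluster_levels))
}

#' Per-leg regression of required support on isometric force
#'
#' Fits, separately for each leg, a linear model of the knee initial-swing
#' stiffness (percent) on the normalized isometric force of the same leg
#' (Nm/kg), over the per-patient aggregated data.
#'
#' @param clinical_table An `ags_clinical_table` from
#'   [prepare_clinical_features()].
#' @return A tibble with columns `leg`, `intercept`, `slope`, `r_squared`,
#'   `p_value`, `n`.
#' @export
lforce_ags_regression <- function(clinical_table) {
  out <- lapply(c("left", "right"), function(leg) {
    df <- tibble(
      k = clinical_table[[paste0("k_knee_is_", leg)]],
      f = clinical_table[[paste0("lforce_", leg)]]
    )
    df <- df[complete.cases(df), ]
    if (nrow(df) < 3L) {
      return(tibble(leg = leg, intercept = NA_real_, slope = NA_real_,
                    r_squared = NA_real_, p_value = NA_real_, n = nrow(df)))
    }
    fit <- lm(k ~ f, data = df)
    sm <- summary(fit)
    tibble(leg = leg, intercept = coef(fit)[1L], slope = coef(fit)[2L],
           r_squared = sm$r.squared,
           p_value = sm$coefficients["f", "Pr(>|t|)"], n = nrow(df))
  })
  bind_rows(out)
}

#' Summarise training exposure of a cohort
#'
#' Number of adaptive training sessions per patient with the mean (to one
#' decimal), minimum and maximum across patients.
#'
#' @param x An `ags_study`, or a numeric vector of per-patient session
#'   counts.
#' @param ... Unused.
#' @return An object of class `ags_cohort_summary` with fields `counts`,
#'   `mean`, `min`, `max`.
#' @examples
#' cohort_summary(c(16, 12, 8, 8, 10, 8, 8, 8, 13, 8))
#' @export
cohort_summary <- function(x, ...) UseMethod("cohort_summary")

#' @export
cohort_summary.numeric <- function(x, ...) {
  if (length(x) < 1L) stop_invalid("need at least one patient.")
  structure(
    list(counts = x, mean = round(mean(x), 1), min = min(x), max = max(x)),
    class = "ags_cohort_summary"
  )
}

#' @export
cohort_summary.ags_study <- function(x, ...) {
  counts <- x$sessions %>%
    group_by(.data$patient_id) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  out <- cohort_summary(as.numeric(counts$n))
  out$counts <- setNames(counts$n, counts$patient_id)
  out
}

#' @export
print.ags_cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<ags_cohort_summary> %d patients | sessions per patient: mean %.1f, min %d, max %d\n",
    length(x$counts), x$mean, as.integer(x$min), as.integer(x$max)
  ))
  invisible(x)
}
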