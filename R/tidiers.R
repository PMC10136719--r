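#' Tidy a paired support comparison
#'
#' @param x An `ags_paired_test`.
#' @param ... Unused.
#' @return A one-row tibble with the mean difference, test statistic,
#'   degrees of freedom, p-value and normality-check p-value.
#' @export
tidy.ags_paired_test <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p_value, shapiro.p = x$shapiro_p, n = x$n,
         degenerate = x$degenerate)
}

#' @rdname tidy.ags_paired_test
#' @export
glance.ags_paired_test <- function(x, ...) tidy.ags_paired_test(x, ...)

#' Tidy a forward-selection result
#'
#' @param x An `ags_selection`.
#' @param ... Unused.
#' @return A tibble of the final model's coefficients with the entry
#'   p-value of each selected variable.
#' @export
tidy.ags_selection <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  out <- tibble(
    term = rownames(cf), estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"], statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
  if (nrow(x$steps) > 0L) {
    out <- left_join(out, rename(x$steps, term = "variable"), by = "term")
  } else {
    out$step <- NA_integer_
    out$p_entry <- NA_real_
  }
  out
}

#' @rdname tidy.ags_selection
#' @export
glance.ags_selection <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n,
         n.selected = length(x$selected),
         alpha.enter = x$alpha_enter)
}

#' Tidy an exponential-decay fit
#'
#' @param x An `ags_decay_fit`.
#' @param ... Unused.
#' @return A one-row tibble with amplitude, rate, plateau, RMSE and the
#'   plateau-detection flag.
#' @export
tidy.ags_decay_fit <- function(x, ...) {
  tibble(amplitude = x$amplitude, rate = x$rate, plateau = x$plateau,
         rmse = x$rmse, plateau.detected = x$plateau_detected)
}

#' @rdname tidy.ags_decay_fit
#' @export
glance.ags_decay_fit <- function(x, ...) {
  tibble(rmse = x$rmse, n = length(x$values),
         span = max(x$cycles) - min(x$cycles),
         plateau.detected = x$plateau_detected)
}

#' Tidy a Bland-Altman agreement analysis
#'
#' @param x An `ags_bland_altman`.
#' @param ... Unused.
#' @return A one-row tibble with bias, limits of agreement and their size
#'   as a percentage of the mean.
#' @export
tidy.ags_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd.diff = x$sd_diff, loa.low = x$loa_low,
         loa.high = x$loa_high, half.width = x$half_width,
         loa.pct.of.mean = x$loa_pct_of_mean,
         loa.pct.full.width = x$loa_pct_full_width, n = x$n)
}
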