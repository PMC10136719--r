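# Internal validation and error helpers. All classed conditions use the
# "adaptgait_error_*" prefix so callers can test on condition class.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "adaptgait_error_invalid_parameter", ...)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = "adaptgait_error_domain", ...)
}

stop_insufficient <- function(msg, ...) {
  abort(msg, class = "adaptgait_error_insufficient_data", ...)
}

stop_schema <- function(msg, ...) {
  abort(msg, class = "adaptgait_error_schema", ...)
}

stop_integrity <- function(msg, ...) {
  abort(msg, class = "adaptgait_error_integrity", ...)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "adaptgait_error_data", ...)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_fraction_domain <- function(fraction) {
  if (!is.numeric(fraction) || any(!is.finite(fraction)) ||
      any(fraction < 0) || any(fraction >= 1)) {
    stop_domain("`fraction` must lie in [0, 1).")
  }
  invisible(fraction)
}

# Seed an RNG stream if a seed is supplied; otherwise leave the current
# stream untouched so callers can manage reproducibility themselves.
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop_invalid("`seed` must be a single finite number.")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# bare column names used in pipeline_analyze's tidy-eval calls
utils::globalVariables(c("ags_mean", "conventional_mean", "speed_10mwt",
                         "tug_s", "day", "value", "lforce_mean", "k_knee_is"))
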