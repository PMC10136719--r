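#' Adaptive impedance controller configuration
#'
#' Constants of the windowed assist-as-needed adaptation law. At every
#' completed gait cycle `s` and in every window `w`, normalized stiffness and
#' damping of the active leg are updated as
#' `K[s+1, w] = clamp(gamma_k * K[s, w] + gain_k * f_k[s, w])` (and the
#' analogous rule for damping driven by the angular-velocity error), where
#' `f` is the deadband-clipped mean absolute tracking deviation divided by
#' the error scale. The forgetting factor `gamma < 1` makes support decay
#' exponentially while the patient tracks well, preventing reliance on the
#' assistance; the gain makes support rise quickly after large deviations.
#'
#' @param gamma_k,gamma_b Forgetting factors per gait cycle, in `(0, 1)`.
#' @param gain_k,gain_b Non-negative adaptation gains.
#' @param deadband_deg Tolerated mean absolute angular deviation in degrees;
#'   deviations at or below it produce no adaptation pressure.
#' @param error_scale_deg Error normalization scale in degrees.
#' @param vel_deadband_dps,vel_scale_dps Deadband and scale for the
#'   angular-velocity error driving the damping update, in deg/s.
#' @param k_min,b_min Safety floor of the normalized impedance (default 4%).
#' @param k_max,b_max Ceiling of the normalized impedance (default 100%).
#' @param k_init,b_init Initial normalized impedance (default 100%).
#' @param sample_ms Logging interval in milliseconds (default 4).
#'
#' @return An object of class `ags_controller_config`.
#' @examples
#' controller_config()
#' @export
controller_config <- function(gamma_k = 0.95, gamma_b = 0.95,
                              gain_k = 0.5, gain_b = 0.5,
                              deadband_deg = 4, error_scale_deg = 10,
                              vel_deadband_dps = 20, vel_scale_dps = 50,
                              k_min = 0.04, b_min = 0.04,
                              k_max = 1, b_max = 1,
                              k_init = 1, b_init = 1,
                              sample_ms = 4) {
  cfg <- structure(
    list(gamma_k = gamma_k, gamma_b = gamma_b, gain_k = gain_k,
         gain_b = gain_b, deadband_deg = deadband_deg,
         error_scale_deg = error_scale_deg,
         vel_deadband_dps = vel_deadband_dps, vel_scale_dps = vel_scale_dps,
         k_min = k_min, b_min = b_min, k_max = k_max, b_max = b_max,
         k_init = k_init, b_init = b_init, sample_ms = sample_ms),
    class = "ags_controller_config"
  )
  validate_controller_config(cfg)
}

validate_controller_config <- function(cfg) {
  if (!inherits(cfg, "ags_controller_config")) {
    stop_invalid("`config` must be created with `controller_config()`.")
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(cfg)) {
    if (!num1(cfg[[nm]])) stop_invalid(sprintf("`%s` must be a finite number.", nm))
  }
  with(cfg, {
    if (gamma_k <= 0 || gamma_k >= 1 || gamma_b <= 0 || gamma_b >= 1) {
      stop_invalid("forgetting factors must lie strictly between 0 and 1.")
    }
    if (gain_k < 0 || gain_b < 0) stop_invalid("gains must be non-negative.")
    if (deadband_deg < 0 || vel_deadband_dps < 0) {
      stop_invalid("deadbands must be non-negative.")
    }
    if (error_scale_deg <= 0 || vel_scale_dps <= 0) {
      stop_invalid("error scales must be positive.")
    }
    if (!(0 < k_min && k_min < k_init && k_init <= k_max && k_max <= 1)) {
      stop_invalid("stiffness bounds must satisfy 0 < k_min < k_init <= k_max <= 1.")
    }
    if (!(0 < b_min && b_min < b_init && b_init <= b_max && b_max <= 1)) {
      stop_invalid("damping bounds must satisfy 0 < b_min < b_init <= b_max <= 1.")
    }
    if (sample_ms <= 0) stop_invalid("`sample_ms` must be positive.")
  })
  cfg
}

#' @export
print.ags_controller_config <- function(x, ...) {
  cat(sprintf(
    paste0("<ags_controller_config> gamma %.3g/%.3g, gain %.3g/%.3g, ",
           "deadband %g deg, floor %g%%, init %g%%\n"),
    x$gamma_k, x$gamma_b, x$gain_k, x$gain_b, x$deadband_deg,
    100 * x$k_min, 100 * x$k_init
  ))
  invisible(x)
}

#' Deadband-clipped error metric
#'
#' Maps a trace of angular deviations within one window to the dimensionless
#' error `f = max(0, mean(|deviation|) - deadband) / scale`: zero whenever
#' the mean absolute deviation stays inside the deadband, and growing
#' linearly beyond it.
#'
#' @param deviation_trace Numeric vector of deviations (degrees, or deg/s for
#'   the velocity error) sampled within one window.
#' @param deadband Deadband in the same units (must be `>= 0`).
#' @param error_scale Positive normalization scale in the same units.
#' @return A single non-negative dimensionless number.
#' @examples
#' error_metric(rep(6, 10), deadband = 4, error_scale = 10) # 0.2
#' @export
error_metric <- function(deviation_trace, deadband = 4, error_scale = 10) {
  if (length(deviation_trace) == 0L) {
    stop_insufficient("`deviation_trace` is empty.")
  }
  if (any(!is.finite(deviation_trace))) stop_data("deviations must be finite.")
  if (deadband < 0) stop_invalid("`deadband` must be non-negative.")
  check_scalar_positive(error_scale, "error_scale")
  max(0, mean(abs(deviation_trace)) - deadband) / error_scale
}

#' Impedance state of the controller
#'
#' Normalized stiffness and damping per joint, leg and window, plus the
#' current cycle counter. Values start at the configured initial impedance
#' (100% by default) and stay within `[floor, ceiling]` after every update.
#'
#' @param config A [controller_config()].
#' @param grid A [window_grid()].
#' @return An object of class `ags_impedance_state` with 3-d arrays `k` and
#'   `b` (joint x leg x window) and `cycle_index`.
#' @examples
#' impedance_state()
#' @export
impedance_state <- function(config = controller_config(), grid = window_grid()) {
  validate_controller_config(config)
  dn <- list(joint = c("hip", "knee"), leg = c("left", "right"),
             window = as.character(seq_len(grid$n_windows) - 1L))
  structure(
    list(
      k = array(config$k_init, dim = c(2L, 2L, grid$n_windows), dimnames = dn),
      b = array(config$b_init, dim = c(2L, 2L, grid$n_windows), dimnames = dn),
      cycle_index = 0L
    ),
    class = "ags_impedance_state"
  )
}

#' @export
print.ags_impedance_state <- function(x, ...) {
  cat(sprintf(
    "<ags_impedance_state> cycle %d; K in [%.3f, %.3f]; B in [%.3f, %.3f]\n",
    x$cycle_index, min(x$k), max(x$k), min(x$b), max(x$b)
  ))
  invisible(x)
}

#' Per-cycle tracking errors
#'
#' Packages one gait cycle's mean absolute angular deviations (`e`, degrees)
#' and angular-velocity deviations (`edot`, deg/s) per joint and window for
#' the active leg, and derives the dimensionless error metrics `f_k`, `f_b`
#' with [error_metric()] semantics.
#'
#' @param e,edot Numeric matrices (2 joints x n windows, hip row first) of
#'   non-negative mean absolute deviations.
#' @param config A [controller_config()] supplying deadbands and scales.
#' @return An object of class `ags_cycle_error` with fields `e`, `edot`,
#'   `f_k`, `f_b`.
#' @export
cycle_error <- function(e, edot = NULL, config = controller_config()) {
  validate_controller_config(config)
  if (!is.matrix(e) || nrow(e) != 2L) {
    stop_invalid("`e` must be a 2 x n_windows matrix (hip and knee rows).")
  }
  if (is.null(edot)) edot <- matrix(0, 2L, ncol(e))
  if (!identical(dim(e), dim(edot))) stop_invalid("`e` and `edot` must match in shape.")
  if (any(e < 0) || any(edot < 0) || any(!is.finite(e)) || any(!is.finite(edot))) {
    stop_data("deviations must be finite and non-negative.")
  }
  structure(
    list(
      e = e, edot = edot,
      f_k = pmax(0, e - config$deadband_deg) / config$error_scale_deg,
      f_b = pmax(0, edot - config$vel_deadband_dps) / config$vel_scale_dps
    ),
    class = "ags_cycle_error"
  )
}

#' Apply one adaptation step to the active leg
#'
#' Updates every joint and window of the active leg with the affine
#' forgetting-factor law and clamps the result into `[floor, ceiling]`
#' afterwards; the inactive leg is left untouched (it is held at full
#' support during one-leg adaptive training). The cycle counter advances.
#'
#' @param state An [impedance_state()].
#' @param errors An [cycle_error()] for the active leg.
#' @param config A [controller_config()].
#' @param active_leg `"left"` or `"right"`.
#' @return The updated `ags_impedance_state`.
#' @examples
#' st <- impedance_state()
#' err <- cycle_error(matrix(0, 2, 30))
#' update_impedance(st, err, active_leg = "left")$k["hip", "left", 1]
#' @export
update_impedance <- function(state, errors, config = controller_config(),
                             active_leg = c("left", "right")) {
  stopifnot(inherits(state, "ags_impedance_state"),
            inherits(errors, "ags_cycle_error"))
  validate_controller_config(config)
  active_leg <- match.arg(active_leg)
  li <- if (active_leg == "left") 1L else 2L
  if (ncol(errors$e) != dim(state$k)[3L]) {
    stop_invalid("error matrices must have one column per window.")
  }
  state$k[, li, ] <- clamp(
    config$gamma_k * state$k[, li, ] + config$gain_k * errors$f_k,
    config$k_min, config$k_max
  )
  state$b[, li, ] <- clamp(
    config$gamma_b * state$b[, li, ] + config$gain_b * errors$f_b,
    config$b_min, config$b_max
  )
  state$cycle_index <- state$cycle_index + 1L
  state
}

#' Analytic stiffness plateau of the deterministic tracking model
#'
#' For a patient whose mean absolute deviation in a window follows the
#' linear model `e = c * (1 - K)` (no noise), the adaptation law has the
#' fixed point `K* = g * (c - d) / (scale * (1 - gamma) + g * c)` whenever
#' the deviation at the fixed point exceeds the deadband `d`; otherwise the
#' deadband branch applies and the stiffness decays to the floor. The result
#' is clamped into the configured bounds.
#'
#' @param c_deg Impairment magnitude(s): mean absolute deviation in degrees
#'   at zero support.
#' @param config A [controller_config()].
#' @return Fixed-point normalized stiffness, same length as `c_deg`.
#' @examples
#' fixed_point_stiffness(20) # 8 / 10.5
#' @export
fixed_point_stiffness <- function(c_deg, config = controller_config()) {
  validate_controller_config(config)
  if (any(c_deg < 0)) stop_invalid("`c_deg` must be non-negative.")
  g <- config$gain_k
  d <- config$deadband_deg
  sc <- config$error_scale_deg
  gam <- config$gamma_k
  kstar <- g * (c_deg - d) / (sc * (1 - gam) + g * c_deg)
  # active-branch fixed point is only self-consistent if the deviation
  # there still exceeds the deadband; otherwise support decays to the floor
  active <- c_deg > d & c_deg * (1 - kstar) > d
  out <- ifelse(active, kstar, config$k_min)
  clamp(out, config$k_min, config$k_max)
}
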