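#' Run one adaptive (assist-as-needed) training block
#'
#' Closed-loop simulation of one-leg adaptive training at the reference
#' cadence. Each gait cycle the patient model produces per-window mean
#' absolute deviations given the current stiffness, the deadband-clipped
#' error metric is evaluated per joint and window, and the active leg's
#' impedance is updated once per completed cycle. The inactive leg is held
#' at full (100%) support throughout.
#'
#' @param patient An `ags_patient` (see [patient_profile()], [sample_cohort()]).
#' @param reference A [gait_reference()] (fixes the cadence).
#' @param config A [controller_config()].
#' @param duration_min Block duration in minutes (> 0; default 5).
#' @param active_leg `"left"` or `"right"`.
#' @param seed Optional seed; the block is fully reproducible given it.
#' @param grid A [window_grid()].
#' @param map A [subphase_map()].
#' @param impairment_scale Multiplier on the patient's impairment for this
#'   block (session-level variability; default 1).
#' @param keep_deviation Keep the per-cycle deviation arrays needed to render
#'   actual joint trajectories into a session log (default `TRUE`).
#' @return An object of class `ags_block` holding per-cycle impedance arrays
#'   (`k`, `b`: joint x window x cycle, values in effect *during* each
#'   cycle), the final state, and the block metadata. Use [session_log()] to
#'   render it into a sampled log and [block_cycles()] for a tidy per-cycle
#'   table.
#' @examples
#' blk <- run_adaptive_block(patient_profile(0), duration_min = 1)
#' tail(block_cycles(blk))
#' @export
run_adaptive_block <- function(patient, reference = gait_reference(),
                               config = controller_config(),
                               duration_min = 5,
                               active_leg = c("left", "right"),
                               seed = NULL, grid = window_grid(),
                               map = subphase_map(),
                               impairment_scale = 1,
                               keep_deviation = TRUE) {
  stopifnot(inherits(patient, "ags_patient"), inherits(reference, "gait_reference"))
  validate_controller_config(config)
  check_scalar_positive(duration_min, "duration_min")
  if (impairment_scale < 0) stop_invalid("`impairment_scale` must be >= 0.")
  active_leg <- match.arg(active_leg)
  set_seed_if(seed)

  nw <- grid$n_windows
  n_cycles <- floor(duration_min * reference$cadence)
  if (n_cycles < 1) stop_invalid("block too short for a single gait cycle.")
  li <- if (active_leg == "left") 1L else 2L
  c_mat <- patient$c[, li, , drop = TRUE] * impairment_scale
  v_mat <- patient$vel_factor[, li, , drop = TRUE]
  dim(c_mat) <- dim(v_mat) <- c(2L, nw)
  sdv <- patient$cycle_variability %||% patient$session_variability

  # flat 60-element state vectors and column-wise storage keep the per-cycle
  # loop allocation-light; the matrices are reshaped to 3-d arrays at the end
  np <- 2L * nw
  c_vec <- as.vector(c_mat)
  v_vec <- as.vector(v_mat)
  K <- rep(config$k_init, np)
  B <- rep(config$b_init, np)
  k_flat <- matrix(NA_real_, np, n_cycles)
  b_flat <- matrix(NA_real_, np, n_cycles)
  dev_flat <- if (keep_deviation) matrix(NA_real_, np, n_cycles) else NULL
  eta <- if (sdv > 0) matrix(rnorm(np * n_cycles, 0, sdv), np, n_cycles) else NULL

  for (s in seq_len(n_cycles)) {
    k_flat[, s] <- K
    b_flat[, s] <- B
    dev <- if (is.null(eta)) c_vec * (1 - K) else c_vec * (1 - K) * (1 + eta[, s])
    dev[dev < 0] <- 0
    if (keep_deviation) dev_flat[, s] <- dev
    f_k <- (dev - config$deadband_deg) / config$error_scale_deg
    f_k[f_k < 0] <- 0
    K <- config$gamma_k * K + config$gain_k * f_k
    K[K < config$k_min] <- config$k_min
    K[K > config$k_max] <- config$k_max
    f_b <- (dev * v_vec - config$vel_deadband_dps) / config$vel_scale_dps
    f_b[f_b < 0] <- 0
    B <- config$gamma_b * B + config$gain_b * f_b
    B[B < config$b_min] <- config$b_min
    B[B > config$b_max] <- config$b_max
  }
  k_arr <- array(k_flat, c(2L, nw, n_cycles))
  b_arr <- array(b_flat, c(2L, nw, n_cycles))
  dev_arr <- if (keep_deviation) array(dev_flat, c(2L, nw, n_cycles)) else NULL
  K <- matrix(K, 2L, nw)
  B <- matrix(B, 2L, nw)

  new_block(
    phase = paste0("adaptive-", active_leg),
    active_leg = active_leg, guidance = NA_real_,
    duration_min = duration_min, cadence = reference$cadence,
    n_cycles = n_cycles, k = k_arr, b = b_arr, dev = dev_arr,
    final_k = K, final_b = B, config = config, grid = grid, map = map,
    reference = reference, patient_id = patient$patient_id
  )
}

#' Run one constant-guidance (conventional) block
#'
#' Conventional training: the therapist-selected guidance force fixes the
#' normalized stiffness and damping of *both* legs for the whole block; no
#' adaptation takes place. The patient model still produces tracking
#' deviations at the corresponding support level.
#'
#' @inheritParams run_adaptive_block
#' @param guidance_force Constant normalized impedance in `(0, 1]`.
#' @param phase Protocol tag for the emitted log (`"conventional"` or
#'   `"warmup"`).
#' @return An `ags_block` (with per-leg deviation arrays).
#' @examples
#' blk <- run_conventional_block(patient_profile(10), guidance_force = 0.6,
#'                               duration_min = 1)
#' blk$guidance
#' @export
run_conventional_block <- function(patient, reference = gait_reference(),
                                   guidance_force, duration_min = 15,
                                   seed = NULL, grid = window_grid(),
                                   map = subphase_map(),
                                   impairment_scale = 1,
                                   phase = c("conventional", "warmup"),
                                   keep_deviation = TRUE) {
  stopifnot(inherits(patient, "ags_patient"), inherits(reference, "gait_reference"))
  if (!is.numeric(guidance_force) || length(guidance_force) != 1L ||
      guidance_force <= 0 || guidance_force > 1) {
    stop_invalid("`guidance_force` must lie in (0, 1].")
  }
  check_scalar_positive(duration_min, "duration_min")
  phase <- match.arg(phase)
  set_seed_if(seed)

  nw <- grid$n_windows
  n_cycles <- floor(duration_min * reference$cadence)
  if (n_cycles < 1) stop_invalid("block too short for a single gait cycle.")
  sdv <- patient$cycle_variability %||% patient$session_variability

  dev <- NULL
  if (keep_deviation) {
    dev <- lapply(1:2, function(li) {
      c_mat <- patient$c[, li, , drop = TRUE] * impairment_scale
      dim(c_mat) <- c(2L, nw)
      eta <- if (sdv > 0) array(rnorm(2L * nw * n_cycles, 0, sdv),
                                c(2L, nw, n_cycles)) else 0
      d <- pmax(0, array(c_mat, c(2L, nw, n_cycles)) * (1 - guidance_force) * (1 + eta))
      dim(d) <- c(2L, nw, n_cycles) # pmax drops the dim attribute
      d
    })
    names(dev) <- c("left", "right")
  }

  k_arr <- array(guidance_force, c(2L, nw, n_cycles))
  new_block(
    phase = phase, active_leg = NA_character_, guidance = guidance_force,
    duration_min = duration_min, cadence = reference$cadence,
    n_cycles = n_cycles, k = k_arr, b = k_arr, dev = dev,
    final_k = matrix(guidance_force, 2L, nw),
    final_b = matrix(guidance_force, 2L, nw),
    config = NULL, grid = grid, map = map,
    reference = reference, patient_id = patient$patient_id
  )
}

new_block <- function(...) structure(list(...), class = "ags_block")

#' @export
print.ags_block <- function(x, ...) {
  cat(sprintf(
    "<ags_block> %s | %g min (%d cycles at %g/min) | final K %.3f-%.3f\n",
    x$phase, x$duration_min, x$n_cycles, x$cadence,
    min(x$final_k), max(x$final_k)
  ))
  invisible(x)
}

#' Per-cycle impedance of a block as a tidy table
#'
#' @param block An `ags_block`.
#' @return A tibble with columns `cycle` (1-based; values in effect during
#'   that cycle), `joint`, `window`, `k`, `b` for the block's adapted leg
#'   (or the constant guidance for conventional blocks).
#' @export
block_cycles <- function(block) {
  stopifnot(inherits(block, "ags_block"))
  nw <- dim(block$k)[2L]
  nc <- dim(block$k)[3L]
  tibble(
    cycle = rep(seq_len(nc), each = 2L * nw),
    joint = rep(rep(c("hip", "knee"), times = nw), times = nc),
    window = rep(rep(seq_len(nw) - 1L, each = 2L), times = nc),
    k = as.vector(block$k),
    b = as.vector(block$b)
  )
}

#' Render blocks into a sampled session log
#'
#' Produces the tabular 4-ms-style log a rehabilitation exoskeleton would
#' record: one row per sample and leg with reference and actual hip/knee
#' angles, the normalized stiffness and damping in effect, the cycle index,
#' cycle fraction, window and protocol phase. During adaptive blocks the
#' inactive leg is logged at constant 100% support with zero deviation.
#'
#' @param ... One or more `ags_block` objects, concatenated in time.
#' @param sample_ms Sampling interval in milliseconds (default 4).
#' @param t0_ms Start time of the first block in ms.
#' @return A tibble of class `ags_session_log` with columns `time_ms`,
#'   `phase`, `active_leg`, `leg`, `cycle_index`, `cycle_fraction`,
#'   `window`, `hip_ref_deg`, `hip_act_deg`, `knee_ref_deg`, `knee_act_deg`,
#'   `k_hip`, `b_hip`, `k_knee`, `b_knee`.
#' @examples
#' blk <- run_adaptive_block(patient_profile(0), duration_min = 0.2)
#' log <- session_log(blk, sample_ms = 100)
#' head(log)
#' @export
session_log <- function(..., sample_ms = 4, t0_ms = 0) {
  blocks <- list(...)
  if (length(blocks) == 1L && is.list(blocks[[1L]]) &&
      !inherits(blocks[[1L]], "ags_block")) {
    blocks <- blocks[[1L]]
  }
  stopifnot(all(vapply(blocks, inherits, logical(1), "ags_block")))
  check_scalar_positive(sample_ms, "sample_ms")
  t0 <- t0_ms
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    out[[i]] <- render_block_log(blocks[[i]], sample_ms, t0)
    t0 <- t0 + blocks[[i]]$duration_min * 60000
  }
  log <- bind_rows(out)
  class(log) <- c("ags_session_log", class(log))
  log
}

render_block_log <- function(block, sample_ms, t0_ms) {
  if (is.null(block$dev)) {
    stop_data("block was simulated without deviation arrays; rerun with `keep_deviation = TRUE`.")
  }
  nw <- block$grid$n_windows
  period_ms <- 60000 / block$cadence
  times <- seq(0, block$duration_min * 60000 - sample_ms, by = sample_ms)
  cyc <- pmin(floor(times / period_ms) + 1L, block$n_cycles)
  frac <- (times - (cyc - 1L) * period_ms) / period_ms
  frac <- pmin(frac, 1 - 1e-12)
  win <- pmin(floor(frac * nw), nw - 1L)

  ref <- block$reference
  hip_ref <- ref$hip_angle(frac)
  knee_ref <- ref$knee_angle(frac)

  leg_rows <- function(leg) {
    adaptive <- grepl("^adaptive", block$phase)
    if (adaptive && !identical(leg, block$active_leg)) {
      k_hip <- k_knee <- b_hip <- b_knee <- rep(1, length(times))
      dev_hip <- dev_knee <- 0
    } else {
      dev_src <- if (adaptive) block$dev else block$dev[[leg]]
      idx_hip <- cbind(1L, win + 1L, cyc)
      idx_knee <- cbind(2L, win + 1L, cyc)
      k_hip <- block$k[idx_hip]
      k_knee <- block$k[idx_knee]
      b_hip <- block$b[idx_hip]
      b_knee <- block$b[idx_knee]
      dev_hip <- dev_src[idx_hip]
      dev_knee <- dev_src[idx_knee]
    }
    tibble(
      time_ms = as.integer(round(t0_ms + times)),
      phase = block$phase,
      active_leg = if (grepl("^adaptive", block$phase)) block$active_leg else NA_character_,
      leg = leg,
      cycle_index = as.integer(cyc),
      cycle_fraction = frac,
      window = as.integer(win),
      hip_ref_deg = hip_ref,
      hip_act_deg = hip_ref - dev_hip,
      knee_ref_deg = knee_ref,
      knee_act_deg = knee_ref - dev_knee,
      k_hip = k_hip, b_hip = b_hip,
      k_knee = k_knee, b_knee = b_knee
    )
  }
  bind_rows(leg_rows("left"), leg_rows("right"))
}
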