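#' Feature-extraction settings
#'
#' @param exclusion_min Minutes discarded from the start of each adaptive
#'   block: the support starts at 100% and needs time to decay to a level
#'   the patient can actually influence (default 1).
#' @param last_minutes Fallback window: when no plateau is detected, the
#'   feature is the mean of the last this-many minutes of the block
#'   (default 4).
#' @param plateau_lambda_span Minimum `rate * cycle-span` for a fitted decay
#'   to count as plateaued; 3 time constants means ~95% settled (default 3).
#' @param plateau_rmse Maximum fit RMSE (normalized impedance units) for a
#'   plateau to be trusted (default 0.05).
#' @param min_points Minimum cycles required for a decay fit (default 10).
#' @return A list of class `ags_feature_config`.
#' @export
feature_config <- function(exclusion_min = 1, last_minutes = 4,
                           plateau_lambda_span = 3, plateau_rmse = 0.05,
                           min_points = 10) {
  structure(as.list(environment()), class = "ags_feature_config")
}

#' Per-cycle subphase means of a session log
#'
#' For every leg, gait cycle and analyzed swing subphase (IS, MS, TS) in the
#' log, computes the mean of each logged impedance quantity (stiffness and
#' damping of hip and knee) over the samples falling in that subphase. A
#' sample's subphase is that of its adaptation window (windows straddling a
#' subphase boundary belong to the majority subphase), so the features
#' aggregate whole windows. Stance samples never contribute.
#'
#' @param log An `ags_session_log` (or any data frame with its columns).
#' @param map A [subphase_map()].
#' @return An `ags_subphase_series` tibble with columns `leg`, `joint`,
#'   `quantity` (`"K"` or `"B"`), `subphase`, `cycle`, `value`, carrying the
#'   inferred cadence and duration as attributes.
#' @export
per_cycle_subphase_means <- function(log, map = subphase_map()) {
  required <- c("leg", "cycle_index", "window", "k_hip", "b_hip", "k_knee", "b_knee")
  missing_cols <- setdiff(required, names(log))
  if (length(missing_cols) > 0L) {
    stop_schema(paste0("log is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (nrow(log) == 0L) stop_insufficient("log has no rows.")
  nw <- max(log$window) + 1L
  grid <- window_grid(nw)
  phase_of_window <- window_subphases(grid, map)

  df <- as_tibble(log[required])
  df$subphase <- phase_of_window[df$window + 1L]
  swing <- df[df$subphase != "stance", , drop = FALSE]
  if (nrow(swing) == 0L) {
    stop_insufficient("log has no swing-phase samples.")
  }
  dropped <- setdiff(unique(df$cycle_index), unique(swing$cycle_index))
  if (length(dropped) > 0L) {
    warn(sprintf("%d cycle(s) without swing samples were skipped.", length(dropped)))
  }

  long <- swing %>%
    tidyr::pivot_longer(all_of(c("k_hip", "b_hip", "k_knee", "b_knee")),
                        names_to = "channel", values_to = "value") %>%
    mutate(
      quantity = if_else(substr(.data$channel, 1, 1) == "k", "K", "B"),
      joint = if_else(grepl("hip", .data$channel), "hip", "knee")
    ) %>%
    group_by(.data$leg, .data$joint, .data$quantity, .data$subphase,
             cycle = .data$cycle_index) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    mutate(subphase = factor(as.character(.data$subphase),
                             levels = c("IS", "MS", "TS"))) %>%
    arrange(.data$leg, .data$joint, .data$quantity, .data$subphase, .data$cycle)

  n_cycles <- max(log$cycle_index)
  duration_min <- infer_log_duration_min(log)
  new_subphase_series(long, cadence = n_cycles / duration_min,
                      duration_min = duration_min)
}

infer_log_duration_min <- function(log) {
  if (!"time_ms" %in% names(log)) return(NA_real_)
  ts <- log$time_ms
  dt <- stats::median(diff(sort(unique(ts))))
  (max(ts) - min(ts) + dt) / 60000
}

new_subphase_series <- function(df, cadence, duration_min) {
  attr(df, "cadence") <- cadence
  attr(df, "duration_min") <- duration_min
  class(df) <- unique(c("ags_subphase_series", class(df)))
  df
}

#' Discard the initial adaptation transient
#'
#' Removes the gait cycles that start within the first `exclusion_min`
#' minutes of the block: the normalized stiffness starts at 100% and decays
#' exponentially, so early cycles reflect the controller's initialization,
#' not the patient. Cycle `s` (1-based) starts at `(s - 1) / cadence`
#' minutes.
#'
#' @param series An `ags_subphase_series` (or a tibble with a `cycle`
#'   column).
#' @param cadence Gait cycles per minute; taken from the series attribute
#'   when omitted.
#' @param exclusion_min Minutes to discard (default 1; 0 is the identity).
#' @return The filtered series, order preserved.
#' @export
discard_warmup <- function(series, cadence = NULL, exclusion_min = 1) {
  if (is.null(cadence)) cadence <- attr(series, "cadence")
  if (is.null(cadence) || !is.finite(cadence)) {
    stop_invalid("`cadence` must be supplied when the series carries none.")
  }
  if (exclusion_min < 0) stop_invalid("`exclusion_min` must be >= 0.")
  if (exclusion_min == 0) return(series)
  start_min <- (series$cycle - 1) / cadence
  keep <- start_min >= exclusion_min
  if (!any(keep)) {
    stop_insufficient("series lies entirely within the exclusion window.")
  }
  out <- series[keep, , drop = FALSE]
  attr(out, "cadence") <- cadence
  attr(out, "duration_min") <- attr(series, "duration_min")
  out
}

#' Fit an exponential decay with plateau
#'
#' Least-squares fit of `y(s) = A * exp(-lambda * s) + C` with `A >= 0` and
#' `lambda >= 0` to an ordered per-cycle series. The rate is found by a
#' deterministic grid search refined with one-dimensional optimization
#' (variable projection: for each candidate rate the amplitude and plateau
#' are solved in closed form), so the fit cannot fail to converge. A
#' plateau is declared detected when the series spans at least
#' `plateau_lambda_span` time constants of the fitted rate *and* the fit
#' RMSE is at most `plateau_rmse`; otherwise downstream feature extraction
#' falls back to the last-minutes mean.
#'
#' @param values Ordered per-cycle values (>= `min_points` of them).
#' @param cycles Optional cycle indices (defaults to `1:length(values)`).
#' @param config An [feature_config()].
#' @param lambda_max Upper bound of the rate search, per cycle (default 2).
#' @return An object of class `ags_decay_fit` with fields `amplitude`,
#'   `rate`, `plateau`, `rmse`, `plateau_detected`, `fitted`, `cycles`,
#'   `values`.
#' @examples
#' s <- 0:199
#' fit <- fit_decay(0.5 * exp(-0.05 * s) + 0.1, cycles = s)
#' fit$plateau
#' @export
fit_decay <- function(values, cycles = NULL, config = feature_config(),
                      lambda_max = 2) {
  if (any(!is.finite(values))) stop_data("`values` must be finite.")
  n <- length(values)
  if (n < config$min_points) {
    stop_insufficient(sprintf("decay fit needs at least %d points.", config$min_points))
  }
  if (is.null(cycles)) cycles <- seq_len(n)
  if (length(cycles) != n) stop_invalid("`cycles` must match `values` in length.")
  s <- cycles - cycles[1L]
  span <- max(s)
  ybar <- mean(values)
  yc <- values - ybar
  syy <- sum(yc^2)

  # variable projection: closed-form LS for (A >= 0, C) at a fixed rate
  solve_lambda <- function(lam) {
    b <- exp(-lam * s)
    bc <- b - mean(b)
    sbb <- sum(bc^2)
    a_hat <- if (sbb < 1e-14) 0 else max(0, sum(bc * yc) / sbb)
    c_hat <- ybar - a_hat * mean(b)
    list(a = a_hat, c = c_hat,
         rss = syy - 2 * a_hat * sum(bc * yc) + a_hat^2 * sbb)
  }

  # vectorized rate grid, then local 1-d refinement of the best bracket
  grid <- c(0, exp(seq(log(1e-4), log(lambda_max), length.out = 25L)))
  E <- exp(-s %o% grid)
  ebar <- colMeans(E)
  n_s <- length(s)
  sbb <- colSums(E^2) - n_s * ebar^2
  sby <- colSums(E * yc)
  a_grid <- ifelse(sbb < 1e-14, 0, pmax(0, sby / sbb))
  rss_grid <- syy - 2 * a_grid * sby + a_grid^2 * sbb
  best <- which.min(rss_grid)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  lam <- if (hi > lo) {
    optimize(function(l) solve_lambda(l)$rss, c(lo, hi), tol = 1e-8)$minimum
  } else {
    grid[best]
  }
  if (rss_grid[best] < solve_lambda(lam)$rss) lam <- grid[best]

  sol <- solve_lambda(lam)
  rmse <- sqrt(sol$rss / n)
  structure(
    list(
      amplitude = sol$a, rate = lam, plateau = sol$c, rmse = rmse,
      plateau_detected = (lam * span >= config$plateau_lambda_span) &&
        (rmse <= config$plateau_rmse),
      fitted = sol$a * exp(-lam * s) + sol$c,
      cycles = cycles, values = values
    ),
    class = "ags_decay_fit"
  )
}

#' @export
print.ags_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<ags_decay_fit> y = %.4f * exp(-%.4f s) + %.4f | rmse %.4f | plateau %s\n",
    x$amplitude, x$rate, x$plateau, x$rmse,
    if (x$plateau_detected) "detected" else "not detected"
  ))
  invisible(x)
}

#' Extract the 12 per-leg subphase features of a session
#'
#' The full per-session feature chain: per-cycle subphase means, exclusion
#' of the initial transient, an exponential-decay fit per series, and per
#' series either the fitted plateau (when detected) or the mean of the last
#' minutes of the block as fallback. This yields 12 values per leg:
#' stiffness and damping for knee and hip in each of the three swing
#' subphases.
#'
#' @param x An `ags_session_log` (rendered or read from CSV), an
#'   `ags_subphase_series`, or an `ags_training_session` from a simulated
#'   study.
#' @param config An [feature_config()].
#' @param ... Passed between methods.
#' @return An `ags_features` tibble with columns `leg`, `quantity`, `joint`,
#'   `subphase`, `value` (normalized impedance fraction), `method`
#'   (`"plateau-fit"` or `"last-4-min-mean"`).
#' @export
extract_session_features <- function(x, config = feature_config(), ...) {
  UseMethod("extract_session_features")
}

#' @export
extract_session_features.ags_subphase_series <- function(x, config = feature_config(), ...) {
  features_from_series(x, config)
}

#' @export
extract_session_features.ags_session_log <- function(x, config = feature_config(), ...) {
  phases <- unique(x$phase[grepl("^adaptive", x$phase)])
  if (length(phases) == 0L) {
    # constant-guidance log: features are the per-subphase means themselves
    series <- per_cycle_subphase_means(x)
    return(features_from_series(series, config))
  }
  out <- lapply(phases, function(ph) {
    leg <- sub("^adaptive-", "", ph)
    rows <- x[x$phase == ph & x$leg == leg, , drop = FALSE]
    class(rows) <- setdiff(class(x), "ags_session_log")
    series <- per_cycle_subphase_means(rows)
    feats <- features_from_series(series, config)
    feats$leg <- leg
    feats
  })
  feats <- bind_rows(out)
  class(feats) <- unique(c("ags_features", class(feats)))
  feats
}

#' @export
extract_session_features.data.frame <- function(x, config = feature_config(), ...) {
  class(x) <- unique(c("ags_session_log", class(x)))
  extract_session_features.ags_session_log(x, config, ...)
}

#' @export
extract_session_features.ags_training_session <- function(x, config = feature_config(), ...) {
  feats <- bind_rows(
    features_from_block(x$blocks$adaptive_left, config),
    features_from_block(x$blocks$adaptive_right, config)
  )
  class(feats) <- unique(c("ags_features", class(feats)))
  feats
}

# Same feature chain as the sampled-log route, computed straight from a
# block's per-cycle impedance arrays (no log rendering, no tibble joins).
features_from_block <- function(block, config) {
  phases <- window_subphases(block$grid, block$map)
  nc <- block$n_cycles
  start_min <- (seq_len(nc) - 1) / block$cadence
  keep <- start_min >= config$exclusion_min
  if (!any(keep)) {
    stop_insufficient("block lies entirely within the exclusion window.")
  }
  in_last <- start_min >= block$duration_min - config$last_minutes
  cyc <- which(keep)

  n_rows <- 12L
  leg <- rep(block$active_leg, n_rows)
  quantity <- character(n_rows); joint <- character(n_rows)
  subphase <- character(n_rows); value <- numeric(n_rows)
  method <- character(n_rows)
  i <- 0L
  for (sp in c("IS", "MS", "TS")) {
    wins <- which(phases == sp)
    for (j in 1:2) {
      for (q in c("K", "B")) {
        arr <- if (q == "K") block$k else block$b
        y <- .colMeans(arr[j, wins, ], length(wins), nc)
        fit <- try_fit(y[keep], cyc, config)
        i <- i + 1L
        quantity[i] <- q
        joint[i] <- c("hip", "knee")[j]
        subphase[i] <- sp
        if (!is.null(fit) && fit$plateau_detected) {
          value[i] <- fit$plateau
          method[i] <- "plateau-fit"
        } else {
          value[i] <- mean(y[in_last])
          method[i] <- "last-4-min-mean"
        }
      }
    }
  }
  tibble(leg = leg, quantity = quantity, joint = joint,
         subphase = subphase, value = value, method = method)
}

# Per-cycle subphase means straight from a block's impedance arrays (the
# sampled-log route gives the same numbers; this one skips the rendering).
block_subphase_series <- function(block) {
  phases <- window_subphases(block$grid, block$map)
  nc <- block$n_cycles
  rows <- list()
  for (sp in c("IS", "MS", "TS")) {
    wins <- which(phases == sp)
    for (j in 1:2) {
      kv <- colMeans(matrix(block$k[j, wins, ], nrow = length(wins)))
      bv <- colMeans(matrix(block$b[j, wins, ], nrow = length(wins)))
      joint <- c("hip", "knee")[j]
      rows[[length(rows) + 1L]] <- tibble(
        leg = block$active_leg %||% NA_character_,
        joint = joint, quantity = "K", subphase = sp,
        cycle = seq_len(nc), value = kv
      )
      rows[[length(rows) + 1L]] <- tibble(
        leg = block$active_leg %||% NA_character_,
        joint = joint, quantity = "B", subphase = sp,
        cycle = seq_len(nc), value = bv
      )
    }
  }
  df <- bind_rows(rows)
  df$subphase <- factor(df$subphase, levels = c("IS", "MS", "TS"))
  new_subphase_series(df, cadence = block$cadence,
                      duration_min = block$duration_min)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

features_from_series <- function(series, config) {
  cadence <- attr(series, "cadence")
  duration_min <- attr(series, "duration_min")
  kept <- discard_warmup(series, cadence, config$exclusion_min)
  groups <- dplyr::group_split(group_by(kept, .data$leg, .data$joint,
                                        .data$quantity, .data$subphase))
  feats <- lapply(groups, function(g) {
    fit <- try_fit(g$value, g$cycle, config)
    if (!is.null(fit) && fit$plateau_detected) {
      value <- fit$plateau
      method <- "plateau-fit"
    } else {
      last_start <- duration_min - config$last_minutes
      in_last <- (g$cycle - 1) / cadence >= last_start
      value <- mean(g$value[in_last])
      method <- "last-4-min-mean"
    }
    tibble(leg = g$leg[1L], quantity = g$quantity[1L], joint = g$joint[1L],
           subphase = as.character(g$subphase[1L]), value = value,
           method = method)
  })
  out <- bind_rows(feats)
  class(out) <- unique(c("ags_features", class(out)))
  out
}

try_fit <- function(values, cycles, config) {
  tryCatch(
    fit_decay(values, cycles, config),
    adaptgait_error_insufficient_data = function(e) NULL
  )
}

#' Average session features over the two legs
#'
#' Elementwise mean of the left- and right-leg features, yielding the 6
#' stiffness and 6 damping values per session used in the clinical analyses.
#' If one leg is missing (e.g. an excluded leg-session), the available leg is
#' propagated with a warning.
#'
#' @param features An `ags_features` tibble for one session.
#' @return A tibble with columns `quantity`, `joint`, `subphase`, `value`.
#' @export
aggregate_over_legs <- function(features) {
  stopifnot(all(c("leg", "quantity", "joint", "subphase", "value") %in% names(features)))
  legs <- unique(features$leg)
  if (length(legs) == 1L) {
    warn(sprintf("only the %s leg is present; propagating it unaveraged.", legs))
  }
  features %>%
    group_by(.data$quantity, .data$joint, .data$subphase) %>%
    summarise(value = mean(.data$value), .groups = "drop")
}
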