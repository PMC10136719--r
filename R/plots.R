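#' Plot the per-cycle stiffness adaptation of a block
#'
#' Stiffness trajectories of every window, colored by gait subphase and
#' faceted by joint: the exponential settling of the assist-as-needed
#' support towards its per-window plateau.
#'
#' @param object An `ags_block`.
#' @param quantity `"k"` (stiffness) or `"b"` (damping).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ags_block <- function(object, quantity = c("k", "b"), ...) {
  quantity <- match.arg(quantity)
  df <- block_cycles(object)
  phases <- window_subphases(object$grid, object$map)
  df$subphase <- phases[df$window + 1L]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$cycle, y = 100 * .data[[quantity]],
    group = .data$window, colour = .data$subphase
  )) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~joint) +
    ggplot2::labs(
      x = "gait cycle",
      y = sprintf("normalized %s (%%)",
                  if (quantity == "k") "stiffness" else "damping"),
      colour = "subphase",
      title = sprintf("Adaptive support, %s block", object$phase)
    )
}

#' Plot an exponential-decay fit
#'
#' @param object An `ags_decay_fit`.
#' @param ... Unused.
#' @return A ggplot object: the per-cycle values, the fitted curve and the
#'   plateau line.
#' @export
autoplot.ags_decay_fit <- function(object, ...) {
  df <- tibble(cycle = object$cycles, value = object$values,
               fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_hline(yintercept = object$plateau, linetype = "dashed") +
    ggplot2::labs(
      x = "gait cycle", y = "normalized impedance",
      title = sprintf("Decay fit: plateau %.3f (%s)", object$plateau,
                      if (object$plateau_detected) "detected" else "fallback used")
    )
}

#' Bland-Altman plot
#'
#' @param object An `ags_bland_altman`.
#' @param ... Unused.
#' @return A ggplot object with the bias and the 95% limits of agreement.
#' @export
autoplot.ags_bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of the two sessions",
                  y = "difference between sessions",
                  title = "Bland-Altman agreement")
}

#' Paired support-level plot
#'
#' Per-patient adaptive versus conventional mean support with connecting
#' lines, the visual companion of [compare_support_paired()].
#'
#' @param support A tibble from [support_levels()].
#' @return A ggplot object.
#' @export
plot_support_levels <- function(support) {
  df <- tidyr::pivot_longer(support, all_of(c("ags_mean", "conventional_mean")),
                            names_to = "mode", values_to = "support")
  df$mode <- factor(df$mode, levels = c("ags_mean", "conventional_mean"),
                    labels = c("adaptive", "conventional"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = 100 * .data$support,
                                   group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "mean normalized stiffness (%)",
                  title = "Robotic support: adaptive vs conventional")
}

#' Force-versus-control scatter with cluster thresholds
#'
#' @param clustered Output of [cluster_force_vs_control()].
#' @param force_threshold,stiffness_threshold The thresholds used.
#' @return A ggplot object.
#' @export
plot_force_clusters <- function(clustered, force_threshold = 0.4,
                                stiffness_threshold = 30) {
  ggplot2::ggplot(clustered, ggplot2::aes(
    x = .data$lforce_mean, y = .data$k_knee_is, colour = .data$cluster
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = force_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = stiffness_threshold, linetype = "dashed") +
    ggplot2::labs(x = "mean normalized isometric force (Nm/kg)",
                  y = "knee stiffness, initial swing (%)",
                  colour = "subgroup")
}

#' Per-patient stiffness trajectories over the training course
#'
#' Leg-wise knee initial-swing stiffness plateau of every training session,
#' one panel per patient: the longitudinal view of the adaptive data.
#'
#' @param features A per-session feature table from
#'   [extract_study_features()].
#' @return A ggplot object.
#' @export
plot_session_trajectories <- function(features) {
  df <- features %>%
    filter(.data$quantity == "K", .data$joint == "knee",
           .data$subphase == "IS")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$session_index,
                                   y = 100 * .data$value,
                                   colour = .data$leg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~patient_id) +
    ggplot2::labs(x = "training session", y = "knee stiffness IS (%)",
                  colour = "leg")
}
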