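#' @title Plot methods
#' @description ggplot2 views of trials, controller logs and sweeps.
#' @name plotting
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic gait trial
#'
#' Ankle angle and angular velocity against time, with heel strikes
#' marked.
#'
#' @param object A `gait_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_trial <- function(object, ...) {
  hs <- object$time[heel_strikes(object)]
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", "angle", "omega")],
    cols = c("angle", "omega"),
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_vline(xintercept = hs, colour = "grey80",
                        linewidth = 0.25) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          angle = "ankle angle (rad, PF+)",
                          omega = "angular velocity (rad/s)"
                        ))) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Synthetic gait trial") +
    ggplot2::theme_minimal()
}

#' Plot a controller log
#'
#' Stimulation, activation, MTU force and commanded exoskeleton torque
#' against time, with swing phase shaded out via the torque trace.
#'
#' @param object An `nmm_log` from [run_playback()] or [run_adaptive()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmm_log <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "stim", "a", "f_mtu", "torque")],
    cols = c("stim", "a", "f_mtu", "torque"),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel,
                         levels = c("stim", "a", "f_mtu", "torque"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "#31a354") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          stim = "stimulation",
                          a = "activation",
                          f_mtu = "MTU force (N)",
                          torque = "exo torque (Nm)"
                        ))) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Reflex controller log") +
    ggplot2::theme_minimal()
}

#' Plot a condition sweep
#'
#' Average exoskeleton torque and net power per condition, in grid order.
#'
#' @param object An `nmm_sweep` from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nmm_sweep <- function(object, ...) {
  m <- object$metrics
  m$condition <- factor(m$condition, levels = m$condition)
  long <- tidyr::pivot_longer(
    m[, c("condition", "avg_torque", "net_power")],
    cols = c("avg_torque", "net_power"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          avg_torque = "average torque (Nm/kg)",
                          net_power = "net power (W/kg)"
                        ))) +
    ggplot2::labs(x = NULL, y = NULL, title = "Gain/Delay condition sweep") +
    ggplot2::theme_minimal()
}
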