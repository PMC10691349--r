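# ggplot2 helpers for each result type.

#' @export
autoplot.respiratory_trajectory <- function(object, ...) {
  ss <- attr(object, "steady_state")
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$atp_m, .data$delta_psi,
                               colour = .data$time_ms)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = ss, colour = "black", shape = 8,
                        size = 3) +
    ggplot2::labs(x = "mitochondrial ATP fraction",
                  y = "proton gradient", colour = "time (ms)",
                  title = "Respiratory state-space excursion") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
}

#' @export
autoplot.ros_curve <- function(object, ...) {
  mn <- ros_curve_minimum(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$baseline, .data$ros_ss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = mn, colour = "red", size = 2) +
    ggplot2::labs(x = "baseline ATP consumption (per ms)",
                  y = "steady-state ROS",
                  title = "V-shaped ROS vs. consumption")
}

#' @export
autoplot.accounting_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$traces,
                              c("atp", "ros", "ms"),
                              names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = object$spikes,
                        ggplot2::aes(xintercept = .data$time_ms,
                                     colour = .data$label),
                        alpha = 0.4) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL, colour = "spike")
}

#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$baseline, .data$q,
                                       fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "baseline cost (ATP per ms)",
                  y = "per-spike cost Q", fill = "pattern")
}

#' @export
autoplot.network_sim <- function(object, max_neurons = 1000, ...) {
  sp <- object$spikes
  ids <- unique(sp$neuron_id)
  if (length(ids) > max_neurons)
    sp <- dplyr::filter(sp, .data$neuron_id %in%
                          sample(ids, max_neurons))
  ggplot2::ggplot(sp, ggplot2::aes(.data$time_ms, .data$neuron_id,
                                   colour = .data$ms)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$stim_off,
                        linetype = "dashed") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "time (ms)", y = "neuron",
                  colour = "MS at spike",
                  title = "Raster through the driven-to-self-sustained transition")
}

#' @export
autoplot.powerlaw_fit <- function(object, data = NULL, ...) {
  if (is.null(data))
    stop("pass the fitted sample as `data`", call. = FALSE)
  x <- sort(data)
  ccdf <- tibble::tibble(x = x,
                         p = 1 - (seq_along(x) - 1) / length(x))
  tail_p <- mean(data >= object$xmin)
  line <- tibble::tibble(
    x = seq(object$xmin, max(x), length.out = 50))
  line$p <- tail_p * hurwitz_zeta(object$exponent, line$x) /
    hurwitz_zeta(object$exponent, object$xmin)
  ggplot2::ggplot(ccdf, ggplot2::aes(.data$x, .data$p)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "value", y = "P(X ≥ x)",
                  title = sprintf("Power-law fit: alpha = %.2f, xmin = %g",
                                  object$exponent, object$xmin))
}

#' Plot clamp traces with currents separated
#'
#' @param trace a [voltage_clamp()] tibble or the `trace` of a
#'   [current_clamp()] result.
#' @return A ggplot object.
#' @export
plot_clamp_currents <- function(trace) {
  long <- tidyr::pivot_longer(trace, c("i_na", "i_k", "i_a", "i_leak"),
                              names_to = "current")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$value,
                                     colour = .data$current)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "current (pA)")
}
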