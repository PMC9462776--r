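#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a detection-versus-lag curve
#'
#' Detection probability by lag, with binomial error bars when the curve was
#' estimated by Monte Carlo. The dashed line marks the blink regime boundary
#' at 0.5 only as a visual guide.
#'
#' @param object An `ab_curve` from [detection_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ab_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag,
                                            y = .data$detection)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::scale_x_continuous(breaks = object$lag) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "T1-T2 lag", y = "T2 detection probability",
                  title = "Attentional blink detection curve") +
    ggplot2::theme_minimal()
  if (!all(is.na(object$std_error))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$detection - .data$std_error, 0),
                   ymax = pmin(.data$detection + .data$std_error, 1)),
      width = 0.15, colour = "#2c7fb8")
  }
  p
}

#' Plot an attentional-load trial trace
#'
#' Stimulus, deterministic load and realised load over the trial, with the
#' blinking threshold shown as a dashed line when the parameters are attached.
#'
#' @param object An `ab_load` from [attentional_load()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ab_load <- function(object, ...) {
  params <- attr(object, "params")
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$load), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$det_load), colour = "#d7301f",
                       linewidth = 0.8) +
    ggplot2::labs(x = "time (ms)", y = "attentional load",
                  title = "Attentional load (grey: with noise, red: noise-free)") +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    p <- p + ggplot2::geom_hline(yintercept = params$y_b, linetype = "dashed")
  }
  p
}

#' Plot a mental-noise parameter sweep
#'
#' Heat maps over the (mu, sigma) grid of the exact detection probability,
#' the noise-free P3b amplitude and the U-shape event product, with the
#' consistent (time 1, time 2) grid points overlaid as crosses.
#'
#' @param object An `ab_sweep` from [sweep_noise_grid()].
#' @param ... Unused.
#' @return A ggplot object (faceted by quantity).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ab_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$grid,
                              c("detection", "p3b", "ushape"),
                              names_to = "quantity", values_to = "value")
  marks <- dplyr::bind_rows(
    dplyr::distinct(object$pairs, mu = .data$mu1, sigma = .data$sigma1) |>
      dplyr::mutate(set = "time 1"),
    dplyr::distinct(object$pairs, mu = .data$mu2, sigma = .data$sigma2) |>
      dplyr::mutate(set = "time 2")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$sigma)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(mu), y = expression(sigma),
                  title = "Model behaviour in mental-noise parameter space") +
    ggplot2::theme_minimal()
  if (nrow(marks) > 0) {
    p <- p + ggplot2::geom_point(
      data = marks, ggplot2::aes(colour = .data$set), shape = 4, size = 1.5) +
      ggplot2::scale_colour_manual(values = c("time 1" = "#2166ac",
                                              "time 2" = "#b2182b"))
  }
  p
}

#' Plot the training interaction cell means
#'
#' Bar chart of mean T1-evoked P3b amplitude per group, session and blink
#' condition.
#'
#' @param object An `ab_interaction` from [training_interaction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ab_interaction <- function(object, ...) {
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$condition, y = .data$mean_p3b,
                               fill = .data$time)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "T2 outcome", y = "mean model P3b amplitude",
                  title = sprintf(
                    "Training interaction: %.1f%% of time-1 no-blink mean",
                    object$interaction_pct)) +
    ggplot2::theme_minimal()
}
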