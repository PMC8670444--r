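#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a displacement field as an arrow map
#'
#' @param object A [displacement_field()].
#' @param scale Arrow magnification factor.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot displacement_field
#' @export
autoplot.displacement_field <- function(object, scale = 10, ...) {
  df <- dplyr::filter(object, .data$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x_mm + scale * .data$ux_mm,
                   yend = .data$y_mm + scale * .data$uy_mm),
      arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm")),
      linewidth = 0.2, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Displacement field (arrows x%g)", scale)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted 2AFC psychometric curve
#'
#' Observed per-level proportions (sized by trial count), the fitted
#' sigmoid, the chance floor and the threshold read-off.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  tab <- object$table
  g <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$level_um,
                                         y = .data$proportion)) +
    ggplot2::geom_hline(yintercept = object$guess, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_trials), alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(1.5, 4), guide = "none") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "vibration amplitude (µm)",
                  y = "P(comparison judged most slippery)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    xs <- seq(min(tab$level_um), max(tab$level_um), length.out = 200)
    curve <- tibble::tibble(level_um = xs,
                            proportion = predict(object, xs))
    g <- g +
      ggplot2::geom_line(data = curve, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = object$threshold_um,
                          linetype = "dashed", colour = "firebrick")
  }
  g
}

#' Plot interfacial stress profiles of a press simulation
#'
#' @param object A `press_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot press_sim
#' @export
autoplot.press_sim <- function(object, ...) {
  prof <- tidyr::pivot_longer(
    object$profile[, c("r_mm", "p_normal", "p_tangential")],
    cols = c("p_normal", "p_tangential"),
    names_to = "component", values_to = "stress")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$r_mm, y = .data$stress,
                                     colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "radial position (mm)",
                  y = "interfacial line stress (N/mm)",
                  title = sprintf("Stress profiles at %g N (mu = %g)",
                                  object$params$target_force,
                                  object$params$mu)) +
    ggplot2::theme_minimal()
}

#' Plot a divergence-versus-force sweep across friction coefficients
#'
#' @param sweep A tibble from [divergence_vs_force_sweep()].
#' @return A ggplot object.
#' @export
plot_divergence_sweep <- function(sweep) {
  ggplot2::ggplot(dplyr::filter(sweep, .data$phase == "ramp"),
                  ggplot2::aes(x = .data$force_N, y = .data$divergence,
                               colour = factor(.data$mu),
                               group = factor(.data$mu))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "normal force (N)", y = "contacted-skin divergence",
                  colour = "μ") +
    ggplot2::theme_minimal()
}
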