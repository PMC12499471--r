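#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an empirical survival curve
#'
#' Step plot of the product-limit probability of remaining unfrozen versus
#' supercooling degree.
#'
#' @param object A `survival_curve` from [empirical_survival()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_T, y = .data$survival)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Supercooling degree ΔT (K)",
                  y = "Unfrozen fraction χ(ΔT)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted rate model against its assay
#'
#' Overlays the fitted ramp survival curve on the empirical (product-limit)
#' curve of the assay the model would predict at the same protocol.
#'
#' @param object A [fit_rate_model()] result.
#' @param assay Optional [freezing_assay()] to overlay; when omitted only the
#'   fitted curve is drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rate_fit
#' @export
autoplot.rate_fit <- function(object, assay = NULL, ...) {
  mu <- mean_supercooling(object$model, object$protocol)
  grid <- seq(0, 2.5 * mu, length.out = 200)
  fitted <- tibble::tibble(
    delta_T = grid,
    survival = ramp_survival(object$model, object$protocol, grid)
  )
  p <- ggplot2::ggplot(fitted,
                       ggplot2::aes(x = .data$delta_T, y = .data$survival)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.9)
  if (!is.null(assay)) {
    p <- p + ggplot2::geom_step(data = empirical_survival(assay),
                                direction = "hv", colour = "grey30")
  }
  p + ggplot2::labs(x = "Supercooling degree ΔT (K)",
                    y = "Unfrozen fraction χ(ΔT)") +
    ggplot2::theme_minimal()
}

#' Plot a scale-up prediction
#'
#' Predictive ramp survival curve at the target scale with the expected
#' supercooling degree marked.
#'
#' @param object A [predict_scaleup()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scaleup_prediction
#' @export
autoplot.scaleup_prediction <- function(object, ...) {
  ggplot2::ggplot(object$survival,
                  ggplot2::aes(x = .data$delta_T, y = .data$survival)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mean_delta_T, linetype = 2) +
    ggplot2::labs(x = "Supercooling degree ΔT (K)",
                  y = "Unfrozen fraction",
                  subtitle = sprintf("expected ΔT = %.2f K at S = %g m²",
                                     object$mean_delta_T, object$protocol$S)) +
    ggplot2::theme_minimal()
}

#' Plot a temperature trace
#'
#' @param object A `temperature_trace` tibble (`time_s`, `temp_C`).
#' @param event Optional [detect_nucleation()] result to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot temperature_trace
#' @export
autoplot.temperature_trace <- function(object, event = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$temp_C)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::labs(x = "Time (s)", y = "Temperature (°C)") +
    ggplot2::theme_minimal()
  if (!is.null(event) && isTRUE(event$event)) {
    p <- p + ggplot2::geom_vline(xintercept = event$time_s,
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot a preservation envelope
#'
#' Safe hold temperature versus duration, one line per labelled container
#' area, on a log time axis.
#'
#' @param table An [envelope_table()] result.
#' @return A ggplot object.
#' @export
plot_envelope <- function(table) {
  ggplot2::ggplot(table,
                  ggplot2::aes(x = .data$duration_s / 3600,
                               y = .data$safe_temp_C,
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hold duration (h)", y = "Safe temperature (°C)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the confined-patch barrier transition
#'
#' Barrier ratio versus normalised patch size for a patch geometry, the
#' signature curve of the zero-size effect: flat at the free-cap value above
#' the transition, rising toward the homogeneous barrier as the patch shrinks.
#'
#' @param patch A [patch_geometry()].
#' @param x Grid of normalised sizes `L_max / (2 R_c)`.
#' @return A ggplot object.
#' @export
plot_barrier_transition <- function(patch,
                                    x = 10^seq(-3, 0.3, length.out = 300)) {
  stopifnot(inherits(patch, "patch_geometry"))
  df <- tibble::tibble(x = x, ratio = barrier_ratio_x(x, patch$theta_0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sin(deg2rad(patch$theta_0)),
                        linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(L[max] / (2 * R[c])),
                  y = expression(Delta * G^"*" / Delta * G[homo]^"*")) +
    ggplot2::theme_minimal()
}
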