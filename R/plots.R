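#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted profile
#'
#' Observed profile points (grey) with the fitted EPE curve (red), equal
#' coordinate scales.
#'
#' @param object An `epe_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot epe_fit
#' @export
autoplot.epe_fit <- function(object, ...) {
  fitted_curve <- sample_curve(object$params, n = 720)
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey55") +
    ggplot2::geom_path(data = fitted_curve, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (cm)", y = "y (cm)",
      title = sprintf("EPE fit, RMSE_adj = %.4f", object$rmse_adj)
    ) +
    ggplot2::theme_minimal()
}

#' Predicted vs observed volume scatter
#'
#' One panel per cultivar with the ordinary least squares line (solid) and
#' the identity line (dashed) expected for a perfect solid of revolution.
#'
#' @param records Record table with `v_obs`, `v_pred` and `cultivar`.
#' @return A ggplot.
#' @export
plot_volume_regression <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$v_obs, y = .data$v_pred)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~cultivar, scales = "free") +
    ggplot2::labs(x = expression(V[obs] ~ (cm^3)),
                  y = expression(V[pred] ~ (cm^3))) +
    ggplot2::theme_minimal()
}

#' Allometric log-log scatter
#'
#' Surface area against observed volume on log10 axes with the fitted
#' power law, per cultivar.
#'
#' @param records Record table with `s`, `v_obs` and `cultivar`.
#' @return A ggplot.
#' @export
plot_allometry <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$v_obs, y = .data$s)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "red", linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~cultivar, scales = "free") +
    ggplot2::labs(x = expression(V[obs] ~ (cm^3)),
                  y = expression(S ~ (cm^2))) +
    ggplot2::theme_minimal()
}
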