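#' Volume of the solid of revolution (closed form)
#'
#' Rotating the EPE profile about its length axis gives the volume
#' \deqn{V = \pi \int_{-b}^{b} y^2\,dx
#'   = \frac{4\pi}{315} a^2 b \,(105 + 21 c_1^2 + 42 c_2 + 9 c_2^2 +
#'     18 c_1 c_3 + 5 c_3^2),}
#' a polynomial identity in the shape coefficients (the spheroid case
#' `c = 0` reduces to \eqn{\frac{4}{3}\pi a^2 b}).
#'
#' @param params An [epe_params] object.
#' @return Volume, cm^3.
#' @examples
#' volume_closed_form(epe_params(1, 1)) # sphere: 4*pi/3
#' @export
volume_closed_form <- function(params) {
  p <- stop_if_invalid_params(params)
  4 * pi / 315 * p$a^2 * p$b *
    (105 + 21 * p$c1^2 + 42 * p$c2 + 9 * p$c2^2 + 18 * p$c1 * p$c3 +
       5 * p$c3^2)
}

#' Volume by adaptive quadrature
#'
#' Independent numerical check of [volume_closed_form()]: adaptive quadrature
#' of \eqn{\pi y(x)^2} over \eqn{[-b, b]}. Kept as a separate code path so
#' the closed form can always be cross-validated.
#'
#' @param params An [epe_params] object.
#' @return Volume, cm^3.
#' @export
volume_quadrature <- function(params) {
  p <- stop_if_invalid_params(params)
  q <- stats::integrate(
    function(x) epe_y(x, p)^2,
    lower = -p$b, upper = p$b,
    rel.tol = 1e-12, abs.tol = 1e-10 * p$a^2 * p$b,
    subdivisions = 500L
  )
  if (q$message != "OK") {
    stop("volume quadrature failed: ", q$message, call. = FALSE)
  }
  pi * q$value
}

#' Surface area of the solid of revolution
#'
#' \deqn{S = 2\pi \int_{-b}^{b} y \sqrt{1 + (dy/dx)^2}\, dx.}
#' The slope diverges at the tips while `y` vanishes there; the product has a
#' finite limit. The integral is evaluated after the substitution
#' \eqn{x = b \sin t}, which removes the endpoint singularity: with
#' \eqn{s = \sin t}, the surface element becomes
#' \eqn{y(t)\sqrt{(dx/dt)^2 + (dy/dt)^2}\,dt}, smooth on
#' \eqn{[-\pi/2, \pi/2]}.
#'
#' @param params An [epe_params] object.
#' @return Surface area, cm^2.
#' @examples
#' surface_area(epe_params(1, 1)) # sphere: 4*pi
#' @export
surface_area <- function(params) {
  p <- stop_if_invalid_params(params)
  integrand <- function(t) {
    s <- sin(t)
    ct <- cos(t)
    pol <- epe_poly(s, p)
    dpol <- p$c1 + s * (2 * p$c2 + s * 3 * p$c3)
    y <- p$a * ct * pol
    dxdt <- p$b * ct
    dydt <- p$a * (-s * pol + ct^2 * dpol)
    y * sqrt(dxdt^2 + dydt^2)
  }
  q <- stats::integrate(
    integrand,
    lower = -pi / 2, upper = pi / 2,
    rel.tol = 1e-10, abs.tol = 1e-12 * p$a * p$b,
    subdivisions = 500L
  )
  if (q$message != "OK") {
    stop("surface-area quadrature failed: ", q$message, call. = FALSE)
  }
  2 * pi * q$value
}

#' Shape metrics of an EPE solid of revolution
#'
#' Bundles predicted volume (closed form), surface area (quadrature), length,
#' maximum width and the width-to-length sphericity ratio.
#'
#' @param params An [epe_params] object.
#' @return A one-row tibble with columns `v_pred` (cm^3), `s` (cm^2),
#'   `l`, `w` (cm) and `w_over_l`.
#' @examples
#' shape_metrics(epe_params(1.4, 1.6, 0.1, -0.05, 0.02))
#' @export
shape_metrics <- function(params) {
  p <- stop_if_invalid_params(params)
  lw <- length_width(p)
  tibble::tibble(
    v_pred = volume_closed_form(p),
    s = surface_area(p),
    l = lw[["l"]],
    w = lw[["w"]],
    w_over_l = lw[["w"]] / lw[["l"]]
  )
}
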