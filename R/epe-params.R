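#' Explicit Preston equation parameters
#'
#' Construct and validate the five shape parameters of the explicit Preston
#' equation (EPE), the closed-form egg-profile curve
#' \deqn{y = \pm a \sqrt{1 - (x/b)^2}\,\bigl(1 + c_1 (x/b) + c_2 (x/b)^2 +
#'   c_3 (x/b)^3\bigr),}
#' whose plus and minus branches trace the upper and lower halves of the
#' profile. `a` and `b` are approximately half the fruit's maximum width and
#' half its length (cm); `c1`, `c2`, `c3` are dimensionless asymmetry/shape
#' coefficients. The cubic shape polynomial must stay strictly positive on
#' \eqn{[-b, b]} for the curve to be a simple closed profile; validity is
#' checked by evaluating the polynomial on a 2001-point grid.
#'
#' @param a Half maximum width, cm. Must be positive.
#' @param b Half length, cm. Must be positive.
#' @param c1,c2,c3 Dimensionless shape coefficients (default 0, giving a
#'   spheroid profile).
#' @return An `epe_params` object (named list with elements `a`, `b`, `c1`,
#'   `c2`, `c3`).
#' @examples
#' p <- epe_params(a = 1.4, b = 1.6, c1 = 0.1, c2 = -0.05, c3 = 0.02)
#' epe_y(0.5, p)
#' @export
epe_params <- function(a, b, c1 = 0, c2 = 0, c3 = 0) {
  vals <- c(a = a, b = b, c1 = c1, c2 = c2, c3 = c3)
  if (!all(is.finite(vals))) {
    stop("EPE parameters must be finite numbers", call. = FALSE)
  }
  if (a <= 0 || b <= 0) {
    stop("EPE parameters 'a' and 'b' must be positive", call. = FALSE)
  }
  p <- structure(
    list(a = a, b = b, c1 = c1, c2 = c2, c3 = c3),
    class = "epe_params"
  )
  if (!epe_params_valid(p)) {
    stop(
      "invalid EPE parameters: the shape polynomial ",
      "1 + c1*u + c2*u^2 + c3*u^3 is not strictly positive on [-b, b]",
      call. = FALSE
    )
  }
  p
}

#' @export
print.epe_params <- function(x, ...) {
  cat(
    sprintf(
      "<epe_params> a = %.6g, b = %.6g, c1 = %.6g, c2 = %.6g, c3 = %.6g\n",
      x$a, x$b, x$c1, x$c2, x$c3
    )
  )
  invisible(x)
}

#' Coerce to EPE parameters
#'
#' @param x An `epe_params` object, a named numeric vector, or a one-row data
#'   frame with columns `a`, `b`, `c1`, `c2`, `c3`.
#' @return An `epe_params` object.
#' @export
as_epe_params <- function(x) {
  if (inherits(x, "epe_params")) {
    return(x)
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[, c("a", "b", "c1", "c2", "c3")])
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(epe_params(x[["a"]], x[["b"]], x[["c1"]], x[["c2"]], x[["c3"]]))
  }
  stop("cannot interpret 'x' as EPE parameters", call. = FALSE)
}

# shape polynomial 1 + c1 u + c2 u^2 + c3 u^3 at u = x/b
epe_poly <- function(u, p) {
  1 + u * (p$c1 + u * (p$c2 + u * p$c3))
}

#' Check validity of EPE parameters
#'
#' Positivity of the cubic shape polynomial is checked on a fixed 2001-point
#' grid over \eqn{[-1, 1]} in the scaled coordinate `u = x/b`.
#'
#' @param p An `epe_params` object or a list with fields `a`, `b`, `c1`,
#'   `c2`, `c3`.
#' @return `TRUE` if the parameters define a simple closed profile.
#' @export
epe_params_valid <- function(p) {
  if (!all(is.finite(unlist(p[c("a", "b", "c1", "c2", "c3")])))) {
    return(FALSE)
  }
  if (p$a <= 0 || p$b <= 0) {
    return(FALSE)
  }
  u <- seq(-1, 1, length.out = 2001)
  all(epe_poly(u, p) > 0)
}

stop_if_invalid_params <- function(p) {
  if (!inherits(p, "epe_params")) {
    p <- as_epe_params(p)
  }
  if (!epe_params_valid(p)) {
    stop("invalid EPE parameters", call. = FALSE)
  }
  p
}
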