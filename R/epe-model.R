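#' Evaluate the explicit Preston equation
#'
#' Computes the profile height \eqn{y(x)} of the EPE curve on the upper or
#' lower branch. The two branches are mirror images about the x-axis (the
#' fruit's length axis).
#'
#' @param x Horizontal coordinate(s), cm; must satisfy `|x| <= b`.
#' @param params An [epe_params] object.
#' @param branch `"upper"` (positive y) or `"lower"` (negative y).
#' @return Numeric vector of y-values, cm; exactly 0 at `x = +-b`.
#' @examples
#' epe_y(0, epe_params(2, 3)) # 2
#' @export
epe_y <- function(x, params, branch = c("upper", "lower")) {
  branch <- match.arg(branch)
  params <- stop_if_invalid_params(params)
  if (any(abs(x) > params$b)) {
    stop("'x' outside the curve domain [-b, b]", call. = FALSE)
  }
  u <- x / params$b
  y <- params$a * sqrt(pmax(0, 1 - u^2)) * epe_poly(u, params)
  if (branch == "lower") -y else y
}

#' Analytic derivative of the EPE curve
#'
#' Slope \eqn{dy/dx} of the chosen branch. The derivative diverges at the
#' curve tips `x = +-b` (vertical tangents); evaluation there is an error.
#'
#' @inheritParams epe_y
#' @return Numeric vector of slopes (dimensionless).
#' @export
epe_dydx <- function(x, params, branch = c("upper", "lower")) {
  branch <- match.arg(branch)
  params <- stop_if_invalid_params(params)
  if (any(abs(x) >= params$b)) {
    stop(
      "derivative requested at or beyond the curve tips |x| = b, ",
      "where the tangent is vertical",
      call. = FALSE
    )
  }
  u <- x / params$b
  g <- sqrt(1 - u^2)
  pol <- epe_poly(u, params)
  dpol <- params$c1 + u * (2 * params$c2 + u * 3 * params$c3)
  # d/dx [a g(u) P(u)] = (a/b) (g'(u) P(u) + g(u) P'(u)), g'(u) = -u/g(u)
  dy <- (params$a / params$b) * (-u / g * pol + g * dpol)
  if (branch == "lower") -dy else dy
}

#' Sample the closed EPE curve
#'
#' Traces both branches of the EPE curve as a closed, counterclockwise
#' polygon of `n` approximately arc-length-equidistant points starting at
#' `(-b, 0)` (the pedicel end), i.e. a standardized profile.
#'
#' @param params An [epe_params] object.
#' @param n Number of points (even, at least 10; default 1000, the number of
#'   equidistant points used for digitized fruit profiles).
#' @return A [fruit_profile] tibble with columns `x`, `y` (cm).
#' @examples
#' prof <- sample_curve(epe_params(1, 1), n = 100) # unit circle
#' @export
sample_curve <- function(params, n = 1000) {
  params <- stop_if_invalid_params(params)
  if (n < 10 || n %% 2 != 0) {
    stop("'n' must be an even integer >= 10", call. = FALSE)
  }
  # dense parameterization: theta in [0, 2pi), x = -b cos(theta),
  # y = -a sin(theta) P(-cos(theta)); starts at (-b, 0), runs CCW through
  # the lower branch first
  m <- max(8L * n, 4000L)
  theta <- seq(0, 2 * pi, length.out = m + 1L)
  u <- -cos(theta)
  x <- params$b * u
  y <- -params$a * sin(theta) * epe_poly(u, params)
  # exact closure
  x[m + 1L] <- x[1L]
  y[m + 1L] <- y[1L]
  res <- resample_closed(x, y, n)
  new_fruit_profile(res$x, res$y, standardized = TRUE)
}

# arc-length-equidistant resampling of a closed polygon given as vertex
# sequence with first vertex repeated at the end; returns n points starting
# at the first vertex
resample_closed <- function(x, y, n) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  per <- s[length(s)]
  if (per <= 0) {
    stop("degenerate polygon: zero perimeter", call. = FALSE)
  }
  target <- per * (seq_len(n) - 1L) / n
  list(
    x = stats::approx(s, x, xout = target, ties = "ordered")$y,
    y = stats::approx(s, y, xout = target, ties = "ordered")$y
  )
}

#' Length and maximum width of an EPE shape
#'
#' `L = 2b`; `W` is twice the maximum of the upper branch, located by a
#' dense-grid scan refined with bounded one-dimensional optimization (the
#' maximum need not sit at `x = 0` when the shape is asymmetric).
#'
#' @param params An [epe_params] object.
#' @return Named numeric vector `c(l = , w = )`, cm.
#' @examples
#' length_width(epe_params(1.5, 2)) # c(l = 4, w = 3)
#' @export
length_width <- function(params) {
  params <- stop_if_invalid_params(params)
  f <- function(x) epe_y(x, params)
  grid <- seq(-params$b, params$b, length.out = 2001)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  w <- 2 * max(opt$objective, vals[i])
  c(l = 2 * params$b, w = w)
}
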