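#' Fruit profile point tables
#'
#' A fruit profile is a tibble with columns `x` and `y` (cm) holding an
#' ordered closed boundary of a fruit's 2D silhouette. A *standardized*
#' profile additionally satisfies: the longest chord lies on the x-axis with
#' midpoint at the origin, the first point is `(-L/2, 0)`, traversal is
#' counterclockwise, and consecutive points are approximately equidistant in
#' arc length.
#'
#' @param x,y Numeric coordinate vectors, cm.
#' @param standardized Logical flag; set by [standardize_profile()] and
#'   [sample_curve()].
#' @return A tibble of class `fruit_profile`.
#' @export
new_fruit_profile <- function(x, y, standardized = FALSE) {
  out <- tibble::tibble(x = x, y = y)
  class(out) <- c("fruit_profile", class(out))
  attr(out, "standardized") <- standardized
  out
}

#' @rdname new_fruit_profile
#' @param data A data frame with columns `x` and `y`.
#' @export
as_fruit_profile <- function(data, standardized = FALSE) {
  if (inherits(data, "fruit_profile")) {
    return(data)
  }
  if (!all(c("x", "y") %in% names(data))) {
    stop("a fruit profile needs columns 'x' and 'y'", call. = FALSE)
  }
  if (nrow(data) < 10) {
    stop("a fruit profile needs at least 10 points", call. = FALSE)
  }
  new_fruit_profile(data$x, data$y, standardized = standardized)
}

is_standardized <- function(profile) {
  isTRUE(attr(profile, "standardized"))
}

#' Read / write profile coordinate files
#'
#' Profile coordinates are exchanged as two-column CSV files (`x`, `y`, cm)
#' with a header row, points ordered counterclockwise starting at `(-L/2, 0)`
#' for standardized profiles.
#'
#' @param path File path.
#' @return `read_profile()` returns a [fruit_profile] tibble.
#' @export
read_profile <- function(path) {
  dat <- utils::read.csv(path)
  names(dat)[1:2] <- c("x", "y")
  as_fruit_profile(dat, standardized = TRUE)
}

#' @rdname read_profile
#' @param profile A [fruit_profile] tibble.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(
    x = format_sig(profile$x),
    y = format_sig(profile$y)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fixed 6-significant-digit formatting used for all CSV output so re-runs
# are byte-identical
format_sig <- function(x, digits = 6) {
  formatC(signif(x, digits), digits = digits, format = "g")
}

# signed polygon area (shoelace); positive for counterclockwise traversal
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# ratio of max to min consecutive spacing around the closed polygon
spacing_ratio <- function(profile) {
  x <- c(profile$x, profile$x[1L])
  y <- c(profile$y, profile$y[1L])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  max(seg) / min(seg)
}
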