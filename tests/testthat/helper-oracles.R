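# independent oracles used across test files

# prolate spheroid (half-width a < half-length b) surface area, closed form
spheroid_surface <- function(a, b) {
  if (a == b) {
    return(4 * pi * a^2)
  }
  e <- sqrt(1 - a^2 / b^2)
  2 * pi * a^2 * (1 + (b / (a * e)) * asin(e))
}

# normal-equations simple linear regression with t-based slope CI
ols_oracle <- function(x, y, level = 0.95) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tq <- qt(1 - (1 - level) / 2, df = n - 2)
  list(
    slope = slope,
    intercept = intercept,
    ci = c(slope - tq * se, slope + tq * se),
    r_squared = cor(x, y)^2
  )
}

# random valid EPE parameters for property runs
random_params <- function(n, a_range = c(0.5, 3), b_range = c(0.5, 3),
                          c_range = c(-0.2, 0.2)) {
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    p <- try(
      epe_params(
        runif(1, a_range[1], a_range[2]),
        runif(1, b_range[1], b_range[2]),
        runif(1, c_range[1], c_range[2]),
        runif(1, c_range[1], c_range[2]),
        runif(1, c_range[1], c_range[2])
      ),
      silent = TRUE
    )
    if (!inherits(p, "try-error")) {
      out[[i]] <- p
      i <- i + 1L
    }
  }
  out
}
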