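# helpers to build masks in code
disk_mask <- function(n, radius) {
  cc <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(r, c) (r - cc)^2 + (c - cc)^2 <= radius^2)
}

write_mask_png <- function(mask, invert = FALSE) {
  path <- withr::local_tempfile(fileext = ".png",
                                .local_envir = parent.frame())
  img <- if (invert) mask * 1 else 1 - mask * 1
  png::writePNG(img, path)
  path
}

test_that("binary images are read with automatic phase selection", {
  mask <- disk_mask(101, 30)
  # dark fruit on light background
  expect_equal(read_binary_image(write_mask_png(mask)), mask)
  # light fruit on dark background also works
  expect_equal(read_binary_image(write_mask_png(mask, invert = TRUE)), mask)
  # uniform image: no silhouette
  expect_error(read_binary_image(write_mask_png(matrix(FALSE, 60, 60))),
               "empty foreground")
  # both phases touching the border is ambiguous
  half <- matrix(FALSE, 60, 60)
  half[, 1:30] <- TRUE
  expect_error(read_binary_image(write_mask_png(half)), "ambiguous")
})

test_that("boundary tracing recovers a disk contour within one pixel", {
  mask <- disk_mask(221, 100)
  bnd <- extract_boundary(mask)
  expect_s3_class(bnd, "raw_boundary")
  rad <- sqrt((bnd$row - 111)^2 + (bnd$col - 111)^2)
  expect_true(all(abs(rad - 100) <= 1))
  # closed 8-connected chain: consecutive pixels are neighbours
  d <- pmax(abs(diff(c(bnd$row, bnd$row[1]))),
            abs(diff(c(bnd$col, bnd$col[1]))))
  expect_true(all(d == 1))
  expect_gt(nrow(bnd), 500)
  expect_lt(nrow(bnd), 700)
})

test_that("the largest component is traced and specks are discarded", {
  mask <- disk_mask(121, 40)
  mask[5:8, 5:8] <- TRUE # a 16-px speck
  expect_message(bnd <- extract_boundary(mask), "discarded")
  expect_true(all(bnd$row > 20))
  # a tiny lone component is rejected
  tiny <- matrix(FALSE, 30, 30)
  tiny[15, 15] <- TRUE
  expect_error(extract_boundary(tiny), "50")
})

test_that("scale calibration converts the longest chord to the caliper length", {
  mask <- disk_mask(521, 250) # chord = 500 px
  bnd <- calibrate_scale(extract_boundary(mask), measured_length = 5)
  expect_equal(attr(bnd, "scale"), 0.01, tolerance = 2e-3)
  expect_error(calibrate_scale(extract_boundary(mask), -1), "positive")
})

test_that("standardization aligns, centers and resamples rotated profiles", {
  # ellipse rotated by 30 degrees, traversed from an arbitrary start
  th <- seq(0.3, 0.3 + 2 * pi, length.out = 721)[-721]
  ex <- 2 * cos(th)
  ey <- 1.2 * sin(th)
  rot <- 30 * pi / 180
  d <- data.frame(
    x = cos(rot) * ex - sin(rot) * ey + 4,
    y = sin(rot) * ex + cos(rot) * ey - 7
  )
  st <- standardize_profile(d, n = 1000)
  expect_equal(nrow(st), 1000)
  expect_true(is.finite(max(st$x)))
  # long axis back on x: extremes at +-2, tilt below 0.1 degree
  expect_equal(range(st$x), c(-2, 2), tolerance = 1e-3)
  # residual tilt of the output major axis (second moments)
  ev <- eigen(cov(cbind(st$x, st$y)), symmetric = TRUE)$vectors[, 1]
  tilt <- abs(atan2(ev[2], ev[1])) %% pi
  tilt <- min(tilt, pi - tilt)
  expect_lt(tilt * 180 / pi, 0.1)
  expect_equal(max(st$y), 1.2, tolerance = 1e-3)
  # counterclockwise, first point at (-L/2, ~0), equidistant spacing
  expect_gt(ovogeom:::polygon_area(st$x, st$y), 0)
  expect_equal(st$x[1], -2, tolerance = 1e-3)
  expect_lt(ovogeom:::spacing_ratio(st), 1.1)
})

test_that("standardization is idempotent on standardized profiles", {
  p <- epe_params(1.4, 1.6, 0.1, -0.05, 0.02)
  prof <- sample_curve(p, 1000)
  again <- standardize_profile(prof, n = 1000)
  expect_equal(max(abs(again$x - prof$x)), 0, tolerance = 1e-9)
  expect_equal(max(abs(again$y - prof$y)), 0, tolerance = 1e-9)
  # a full re-standardization pass from bare coordinates stays very close
  redone <- standardize_profile(as.data.frame(prof), n = 1000)
  expect_lt(max(abs(redone$x - prof$x)), 1e-4)
  expect_lt(max(abs(redone$y - prof$y)), 1e-4)
})

test_that("profiles survive a CSV write/read round trip", {
  prof <- sample_curve(epe_params(1.2, 1.5, 0.05), 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$x, prof$x, tolerance = 1e-5)
  expect_equal(back$y, prof$y, tolerance = 1e-5)
})
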