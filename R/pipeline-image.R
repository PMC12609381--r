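#' Read a binary silhouette image
#'
#' Reads a raster image (PNG) and binarizes it at a 50% gray threshold. The
#' fruit silhouette is identified as the phase that does not touch the image
#' border (photographic silhouettes sit inside a background that reaches the
#' edges), so dark-on-light and light-on-dark images are both accepted.
#'
#' @param path Path to a PNG file (grayscale or RGB; RGB is averaged).
#' @return A logical matrix (rows x cols) with `TRUE` for fruit pixels.
#' @export
read_binary_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , 1:min(3L, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  }
  dark <- img < 0.5
  border <- c(dark[1, ], dark[nrow(dark), ], dark[, 1], dark[, ncol(dark)])
  dark_touches <- any(border)
  light_touches <- any(!border)
  if (dark_touches && light_touches) {
    stop(
      "ambiguous silhouette: both dark and light phases touch the image ",
      "border; crop the image so the fruit is surrounded by background",
      call. = FALSE
    )
  }
  mask <- if (dark_touches) !dark else dark
  if (!any(mask)) {
    stop("empty foreground: the image contains no silhouette phase",
         call. = FALSE)
  }
  mask
}

#' Extract the silhouette boundary
#'
#' Traces the outer contour of the largest connected foreground component
#' with Moore-neighbour (8-connected) boundary following, producing a single
#' closed, counterclockwise, ordered pixel chain. Smaller components (noise
#' specks) are discarded with a message.
#'
#' @param mask Logical matrix from [read_binary_image()].
#' @return A `raw_boundary` tibble with columns `row`, `col` (pixel indices)
#'   and attributes `image_shape` and `scale` (cm per pixel, `NA` until
#'   [calibrate_scale()] is applied).
#' @export
extract_boundary <- function(mask) {
  if (!any(mask)) {
    stop("empty mask", call. = FALSE)
  }
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- round(as.matrix(EBImage::imageData(lab)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  if (length(sizes) > 1L) {
    message(length(sizes) - 1L, " smaller component(s) discarded")
  }
  comp <- lab == keep
  chain <- moore_trace(comp)
  if (nrow(chain) < 50L) {
    stop("boundary too small: fewer than 50 boundary pixels", call. = FALSE)
  }
  out <- tibble::as_tibble(chain)
  class(out) <- c("raw_boundary", class(out))
  attr(out, "image_shape") <- dim(mask)
  attr(out, "scale") <- NA_real_
  out
}

# Moore-neighbour contour tracing with Jacob's stopping criterion.
# Returns the ordered outer boundary of the single TRUE component in `comp`
# as a two-column matrix (row, col). The scan of each pixel's Moore
# neighbourhood is clockwise (in image coordinates, row increasing
# downward), starting from the background pixel examined just before the
# current pixel was entered.
moore_trace <- function(comp) {
  nr <- nrow(comp)
  nc <- ncol(comp)
  fg <- function(r, c) {
    r >= 1L && r <= nr && c >= 1L && c <= nc && comp[r, c]
  }
  # clockwise Moore neighbourhood: W, NW, N, NE, E, SE, S, SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dir_index <- function(drr, dcc) which(dr == drr & dc == dcc)
  # start: topmost-then-leftmost foreground pixel; the pixel to its north is
  # guaranteed background and serves as the initial backtrack
  idx <- which(comp)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  r0 <- min(rows)
  c0 <- min(cols[rows == r0])
  start <- c(r0, c0)
  out_r <- integer(0)
  out_c <- integer(0)
  cap <- max(256L, 4L * (nr + nc))
  path <- matrix(0L, nrow = cap, ncol = 2L)
  path[1L, ] <- start
  path_len <- 1L
  cur <- start
  dir0 <- 3L # scan starts at N, the known-background backtrack
  first_move <- NA_integer_
  max_steps <- 8L * length(idx) + 16L
  steps <- 0L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("contour tracing failed to close", call. = FALSE)
    }
    moved <- FALSE
    for (k in 0:7) {
      d <- (dir0 + k - 1L) %% 8L + 1L
      rr <- cur[1L] + dr[d]
      cc <- cur[2L] + dc[d]
      if (fg(rr, cc)) {
        nxt <- c(rr, cc)
        # Jacob's criterion: stop when the trace is back at the start pixel
        # and about to leave it along the same direction as the first move
        if (!is.na(first_move) && path_len > 1L &&
            cur[1L] == start[1L] && cur[2L] == start[2L] &&
            d == first_move) {
          res <- path[seq_len(path_len), , drop = FALSE]
          colnames(res) <- c("row", "col")
          return(res)
        }
        if (is.na(first_move)) first_move <- d
        if (!(nxt[1L] == start[1L] && nxt[2L] == start[2L])) {
          path_len <- path_len + 1L
          if (path_len > nrow(path)) {
            path <- rbind(path, matrix(0L, nrow = nrow(path), ncol = 2L))
          }
          path[path_len, ] <- nxt
        }
        # new backtrack: the neighbour examined just before nxt (background;
        # for k = 0 the scan entry itself, which is the previous backtrack)
        dprev <- (dir0 + k - 2L) %% 8L + 1L
        rel_r <- dr[dprev] - dr[d]
        rel_c <- dc[dprev] - dc[d]
        dir0 <- dir_index(rel_r, rel_c)
        cur <- nxt
        moved <- TRUE
        break
      }
    }
    if (!moved) {
      # isolated single pixel
      res <- path[seq_len(path_len), , drop = FALSE]
      colnames(res) <- c("row", "col")
      return(res)
    }
  }
}

#' Calibrate pixel scale from a caliper length
#'
#' Sets the cm-per-pixel factor of a raw boundary from the fruit's
#' caliper-measured length: `scale = measured_length / longest chord (px)`.
#' The same factor applies to both axes.
#'
#' @param boundary A `raw_boundary` from [extract_boundary()].
#' @param measured_length Caliper length of the fruit, cm.
#' @return The boundary with its `scale` attribute set.
#' @export
calibrate_scale <- function(boundary, measured_length) {
  if (!is.numeric(measured_length) || measured_length <= 0) {
    stop("'measured_length' must be a positive length in cm", call. = FALSE)
  }
  pts <- boundary_to_plane(boundary, scale = 1)
  chord <- longest_chord(pts$x, pts$y)
  if (chord$length <= 0) {
    stop("degenerate boundary: zero-length longest chord", call. = FALSE)
  }
  attr(boundary, "scale") <- measured_length / chord$length
  boundary
}

# pixel (row, col) -> plane (x, y) in cm: pixel centers, y axis flipped so
# y increases upward
boundary_to_plane <- function(boundary, scale = attr(boundary, "scale")) {
  shape <- attr(boundary, "image_shape")
  list(
    x = (boundary$col - 0.5) * scale,
    y = (shape[1] - boundary$row + 0.5) * scale
  )
}

# longest chord between points; ties broken by smallest absolute angle to
# the horizontal. Uses the convex hull to keep the pairwise search small.
longest_chord <- function(x, y) {
  h <- grDevices::chull(x, y)
  xs <- x[h]
  ys <- y[h]
  m <- length(h)
  best <- list(length = -Inf, i = 1L, j = 1L, angle = 0)
  for (i in seq_len(m - 1L)) {
    dx <- xs[(i + 1L):m] - xs[i]
    dy <- ys[(i + 1L):m] - ys[i]
    d2 <- dx^2 + dy^2
    jrel <- which.max(d2)
    d <- sqrt(d2[jrel])
    ang <- atan2(dy[jrel], dx[jrel])
    ang <- atan2(sin(ang), cos(ang)) # normalize
    ang_abs <- abs(atan2(sin(2 * ang), cos(2 * ang)) / 2) # angle mod pi
    if (d > best$length + 1e-12 ||
        (abs(d - best$length) <= 1e-12 && ang_abs < abs(best$angle))) {
      best <- list(
        length = d,
        i = h[i], j = h[i + jrel],
        angle = atan2(sin(2 * ang), cos(2 * ang)) / 2
      )
    }
  }
  best
}

#' Standardize a fruit profile
#'
#' Brings a digitized boundary into the canonical frame used for fitting:
#' the fruit's length axis is rotated onto the x-axis, the boundary is
#' centered at the origin (tip midpoint in x, boundary centroid in y),
#' resampled to `n` arc-length-equidistant points, traversal is
#' counterclockwise, and the first point is the leftmost one,
#' `(-L/2, ~0)`.
#'
#' The axis orientation is the principal axis of the boundary points
#' (second moments). For a clean profile this coincides with the longest
#' chord; on noisy boundaries of nearly round fruits it is far more stable:
#' the longest-chord direction of a noisy near-circular outline is
#' ill-conditioned (its angle error grows like the square root of
#' noise/(L-W)), while the moment axis averages every boundary point.
#'
#' An input that is already standardized (a [fruit_profile] carrying the
#' standardized flag) is returned unchanged: arc-length resampling is not an
#' exact fixed point numerically, so idempotence is guaranteed by
#' recognising the canonical frame rather than by re-running the transform.
#'
#' @param boundary A calibrated `raw_boundary`, or a data frame with columns
#'   `x`, `y` in cm.
#' @param n Number of resampled points (default 1000).
#' @return A standardized [fruit_profile] tibble.
#' @export
standardize_profile <- function(boundary, n = 1000) {
  if (inherits(boundary, "fruit_profile") && is_standardized(boundary) &&
      nrow(boundary) == n) {
    return(boundary)
  }
  if (inherits(boundary, "raw_boundary")) {
    sc <- attr(boundary, "scale")
    if (is.na(sc)) {
      stop("boundary is not calibrated; run calibrate_scale() first",
           call. = FALSE)
    }
    pts <- boundary_to_plane(boundary)
    x <- pts$x
    y <- pts$y
  } else {
    if (!all(c("x", "y") %in% names(boundary))) {
      stop("expected a raw_boundary or a data frame with columns x, y",
           call. = FALSE)
    }
    x <- boundary$x
    y <- boundary$y
  }
  if (length(x) < 10L) {
    stop("too few boundary points to standardize", call. = FALSE)
  }
  if (max(x) == min(x) || max(y) == min(y)) {
    stop("degenerate boundary: zero width or length", call. = FALSE)
  }
  # principal-axis angle in (-pi/2, pi/2]
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
  if (ev[1L] < 0) {
    ev <- -ev
  }
  ang <- atan2(ev[2L], ev[1L])
  ca <- cos(-ang)
  sa <- sin(-ang)
  cx <- mean(x)
  cy <- mean(y)
  xr <- ca * (x - cx) - sa * (y - cy)
  yr <- sa * (x - cx) + ca * (y - cy)
  # center: tip midpoint in x, boundary centroid in y (the revolution axis
  # of a closed profile sampled ~uniformly in arc length)
  xr <- xr - (max(xr) + min(xr)) / 2
  yr <- yr - mean(yr)
  # counterclockwise orientation
  if (polygon_area(xr, yr) < 0) {
    xr <- rev(xr)
    yr <- rev(yr)
  }
  # start the chain at the left chord endpoint (-L/2, 0)
  i0 <- which.min(xr)
  ord <- c(i0:length(xr), seq_len(i0 - 1L))
  xr <- xr[ord]
  yr <- yr[ord]
  res <- resample_closed(c(xr, xr[1L]), c(yr, yr[1L]), n)
  new_fruit_profile(res$x, res$y, standardized = TRUE)
}

#' Digitize a silhouette image into a standardized profile
#'
#' Convenience chain `read_binary_image() |> extract_boundary() |>
#' calibrate_scale() |> standardize_profile()`.
#'
#' @param path PNG silhouette path.
#' @param measured_length Caliper length, cm.
#' @param n Number of resampled profile points.
#' @return A standardized [fruit_profile].
#' @export
digitize_image <- function(path, measured_length, n = 1000) {
  mask <- read_binary_image(path)
  bnd <- extract_boundary(mask)
  bnd <- calibrate_scale(bnd, measured_length)
  standardize_profile(bnd, n = n)
}
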