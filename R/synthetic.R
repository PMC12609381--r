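#' Cohort specification for synthetic fruit generation
#'
#' Defines the distribution a synthetic cohort is drawn from: `a`, `b`
#' uniform in their ranges (cm), shape coefficients Gaussian with the given
#' standard deviations (truncated by resampling to keep the shape polynomial
#' positive), radial digitization noise as a fraction of `a`, and a
#' water-displacement error model for the observed volume (multiplicative
#' Gaussian noise followed by rounding to the cylinder's graduation step).
#'
#' All randomness is driven by R's default Mersenne-Twister generator seeded
#' with `seed`, so cohorts are fully reproducible.
#'
#' @param cultivar Cohort label.
#' @param n_fruits Number of fruits.
#' @param a_range,b_range Length-2 numeric ranges, cm.
#' @param c1_sd,c2_sd,c3_sd Standard deviations of the shape coefficients.
#' @param radial_noise_frac Radial digitization noise, fraction of `a`.
#' @param v_obs_noise_frac Multiplicative sd of the volume measurement.
#' @param v_obs_resolution Rounding step of the graduated cylinder, cm^3.
#' @param seed Mandatory RNG seed.
#' @return A `cohort_spec` object (list).
#' @export
cohort_spec <- function(cultivar, n_fruits, a_range, b_range,
                        c1_sd = 0.03, c2_sd = 0.03, c3_sd = 0.02,
                        radial_noise_frac = 0.01,
                        v_obs_noise_frac = 0.02,
                        v_obs_resolution = 1,
                        seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("'seed' is mandatory for reproducibility", call. = FALSE)
  }
  stopifnot(
    length(a_range) == 2, length(b_range) == 2,
    all(a_range > 0), all(b_range > 0),
    c1_sd >= 0, c2_sd >= 0, c3_sd >= 0,
    radial_noise_frac >= 0, v_obs_noise_frac >= 0, v_obs_resolution > 0,
    n_fruits >= 1
  )
  structure(
    list(
      cultivar = cultivar, n_fruits = as.integer(n_fruits),
      a_range = sort(a_range), b_range = sort(b_range),
      c1_sd = c1_sd, c2_sd = c2_sd, c3_sd = c3_sd,
      radial_noise_frac = radial_noise_frac,
      v_obs_noise_frac = v_obs_noise_frac,
      v_obs_resolution = v_obs_resolution,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Cultivar presets for egg-shaped tomato cohorts
#'
#' Convenience cohort specifications emulating three egg-shaped tomato
#' cultivars. The `a`/`b` ranges are calibrated so that the median
#' width-to-length ratio and the predicted-volume range bracket the values
#' reported for field cohorts of these cultivars (cherry: median W/L 0.90,
#' V 10.3-23.7 cm^3, n = 297; Qianxi: 0.89, 9.9-30.9 cm^3, n = 320; truss:
#' 0.97, 5.0-12.1 cm^3, n = 300). They are convenience defaults, not claims
#' about the true cultivar distributions.
#'
#' @param preset `"cherry"`, `"qianxi"` or `"truss"`.
#' @param n_fruits Cohort size; defaults to the cultivar's field sample
#'   size.
#' @param seed RNG seed (default 20241106).
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
cultivar_preset <- function(preset = c("cherry", "qianxi", "truss"),
                            n_fruits = NULL, seed = 20241106, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    cherry = list(n = 297L, a_range = c(1.30, 1.72), b_range = c(1.45, 1.91)),
    qianxi = list(n = 320L, a_range = c(1.28, 1.87), b_range = c(1.44, 2.10)),
    truss  = list(n = 300L, a_range = c(1.05, 1.41), b_range = c(1.08, 1.45))
  )
  args <- list(
    cultivar = preset,
    n_fruits = if (is.null(n_fruits)) base$n else n_fruits,
    a_range = base$a_range,
    b_range = base$b_range,
    seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(cohort_spec, args)
}

#' Draw EPE parameters from a cohort specification
#'
#' `a`, `b` are uniform in their ranges; shape coefficients are Gaussian and
#' resampled (up to 100 tries) until the shape polynomial is strictly
#' positive. Draws consume the current RNG state; seed it (or use
#' [generate_cohort()], which seeds from the spec) for reproducibility.
#'
#' @param spec A [cohort_spec].
#' @param n Number of parameter draws.
#' @return A tibble with columns `a`, `b`, `c1`, `c2`, `c3`.
#' @export
sample_epe_params <- function(spec, n = 1) {
  draws <- purrr::map(seq_len(n), function(i) {
    a <- stats::runif(1, spec$a_range[1], spec$a_range[2])
    b <- stats::runif(1, spec$b_range[1], spec$b_range[2])
    for (try in seq_len(100)) {
      cs <- stats::rnorm(3, 0, c(spec$c1_sd, spec$c2_sd, spec$c3_sd))
      p <- list(a = a, b = b, c1 = cs[1], c2 = cs[2], c3 = cs[3])
      if (epe_params_valid(p)) {
        return(tibble::tibble(a = a, b = b, c1 = cs[1], c2 = cs[2],
                              c3 = cs[3]))
      }
    }
    stop("could not draw valid shape coefficients in 100 tries; ",
         "the spec's sds are too large", call. = FALSE)
  })
  dplyr::bind_rows(draws)
}

#' Generate a noisy digitized profile
#'
#' Samples the analytic EPE curve, perturbs each point radially from the
#' centroid by a Gaussian noise field with pointwise sd
#' `radial_noise_frac * a`, and re-standardizes. The field is smooth along
#' the contour (a random combination of the first `harmonics` Fourier modes
#' in contour position, scaled to the requested marginal sd): digitization
#' error of this amplitude — a few pixels — comes from blur, shadow and
#' thresholding effects that displace the traced boundary coherently over
#' many pixels, so adjacent samples (spaced well below a pixel of error)
#' cannot jump independently. With zero noise the analytic curve is
#' returned unchanged.
#'
#' @param params An [epe_params] object.
#' @param n Number of profile points.
#' @param radial_noise_frac Pointwise noise sd as a fraction of `a`.
#' @param harmonics Number of Fourier modes of the noise field (default 20,
#'   a correlation scale of a few percent of the perimeter).
#' @return A standardized [fruit_profile].
#' @export
generate_profile <- function(params, n = 1000, radial_noise_frac = 0,
                             harmonics = 20) {
  params <- stop_if_invalid_params(params)
  prof <- sample_curve(params, n = n)
  if (radial_noise_frac <= 0) {
    return(prof)
  }
  cx <- mean(prof$x)
  cy <- mean(prof$y)
  dx <- prof$x - cx
  dy <- prof$y - cy
  r <- sqrt(dx^2 + dy^2)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  ab <- matrix(stats::rnorm(2L * harmonics), ncol = 2L)
  z <- (cos(outer(theta, seq_len(harmonics))) %*% ab[, 1L] +
          sin(outer(theta, seq_len(harmonics))) %*% ab[, 2L]) /
    sqrt(harmonics)
  rn <- r + radial_noise_frac * params$a * as.numeric(z)
  noisy <- data.frame(x = cx + dx / r * rn, y = cy + dy / r * rn)
  standardize_profile(noisy, n = n)
}

#' Simulate a water-displacement volume reading
#'
#' Applies multiplicative Gaussian measurement noise and rounds to the
#' graduated cylinder's resolution (default 1 cm^3), flooring at one
#' graduation step.
#'
#' @param v_true True volume, cm^3 (> 0).
#' @param noise_frac Multiplicative sd.
#' @param resolution Rounding step, cm^3.
#' @return Simulated observed volume(s), cm^3.
#' @export
simulate_v_obs <- function(v_true, noise_frac = 0.02, resolution = 1) {
  if (any(v_true <= 0)) {
    stop("'v_true' must be positive", call. = FALSE)
  }
  v <- v_true * (1 + stats::rnorm(length(v_true), 0, noise_frac))
  v <- round(v / resolution) * resolution
  pmax(v, resolution)
}

#' Render a silhouette image of an EPE shape
#'
#' Rasterizes the filled EPE silhouette (black fruit on white background,
#' pixel centers, at least a 10-pixel margin on every side) at the given
#' scale, 600 dpi by default — the resolution of the photographic
#' digitization chain this emulates.
#'
#' @param params An [epe_params] object.
#' @param path Optional PNG output path; if `NULL` the logical mask is
#'   returned instead.
#' @param cm_per_px Scale (default `2.54/600`, i.e. 600 dpi).
#' @param margin_px Background margin, pixels.
#' @param max_pixels Pixel budget guard.
#' @return The PNG path (invisibly) if `path` is given, otherwise the
#'   logical foreground mask.
#' @export
render_image <- function(params, path = NULL, cm_per_px = 2.54 / 600,
                         margin_px = 20, max_pixels = 2e7) {
  params <- stop_if_invalid_params(params)
  if (cm_per_px <= 0) {
    stop("'cm_per_px' must be positive", call. = FALSE)
  }
  if (margin_px < 10) {
    stop("'margin_px' must be at least 10", call. = FALSE)
  }
  ymax <- length_width(params)[["w"]] / 2
  nc <- ceiling(2 * params$b / cm_per_px) + 2 * margin_px
  nr <- ceiling(2 * ymax / cm_per_px) + 2 * margin_px
  if (as.double(nr) * nc > max_pixels) {
    stop("image would exceed the pixel budget (", nr, " x ", nc, ")",
         call. = FALSE)
  }
  # pixel-center coordinates, origin at the image center, y up
  xs <- ((seq_len(nc)) - 0.5 - nc / 2) * cm_per_px
  ys <- ((nr - seq_len(nr)) + 0.5 - nr / 2) * cm_per_px
  inside_x <- abs(xs) < params$b
  ylim <- numeric(nc)
  ylim[inside_x] <- epe_y(xs[inside_x], params)
  mask <- outer(ys, ylim, function(y, yl) abs(y) <= yl)
  mask[, !inside_x] <- FALSE
  if (is.null(path)) {
    return(mask)
  }
  png::writePNG(1 - mask * 1, path)
  invisible(path)
}

#' Generate a synthetic fruit cohort
#'
#' Draws `n_fruits` shapes from a [cohort_spec], computes their true
#' geometry, generates noisy digitized profiles and simulated
#' water-displacement volumes, and returns one record per fruit with the
#' ground-truth parameters kept alongside (enabling parameter-recovery
#' scoring). Fully deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec].
#' @param n_points Profile points per fruit (default 1000).
#' @param dir Optional directory: per-fruit profile CSVs and a
#'   `manifest.csv` with the ground truth are written there.
#' @return A tibble with columns `fruit_id`, `cultivar`, the ground-truth
#'   shape (`a_true`..`c3_true`, `l_true`, `w_true`, `w_over_l_true`,
#'   `v_true`, `s_true`), the simulated `v_obs`, and a `profile` list-column
#'   of standardized profiles.
#' @export
generate_cohort <- function(spec, n_points = 1000, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  pars <- sample_epe_params(spec, spec$n_fruits)
  recs <- purrr::map(seq_len(spec$n_fruits), function(i) {
    p <- epe_params(pars$a[i], pars$b[i], pars$c1[i], pars$c2[i],
                    pars$c3[i])
    lw <- length_width(p)
    v_true <- volume_closed_form(p)
    s_true <- surface_area(p)
    prof <- generate_profile(p, n = n_points,
                             radial_noise_frac = spec$radial_noise_frac)
    v_obs <- simulate_v_obs(v_true, spec$v_obs_noise_frac,
                            spec$v_obs_resolution)
    tibble::tibble(
      fruit_id = sprintf("%s_%04d", spec$cultivar, i),
      cultivar = spec$cultivar,
      a_true = p$a, b_true = p$b, c1_true = p$c1, c2_true = p$c2,
      c3_true = p$c3,
      l_true = lw[["l"]], w_true = lw[["w"]],
      w_over_l_true = lw[["w"]] / lw[["l"]],
      v_true = v_true, s_true = s_true, v_obs = v_obs,
      profile = list(prof)
    )
  })
  cohort <- dplyr::bind_rows(recs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) {
      dir.create(dir, recursive = TRUE)
    }
    purrr::walk2(cohort$profile, cohort$fruit_id, function(prof, id) {
      write_profile(prof, file.path(dir, paste0(id, ".csv")))
    })
    manifest <- dplyr::mutate(
      dplyr::select(cohort, -"profile"),
      dplyr::across(dplyr::where(is.numeric), ~ format_sig(.x))
    )
    manifest$profile_file <- paste0(cohort$fruit_id, ".csv")
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  cohort
}

#' Fit every profile of a cohort
#'
#' Runs [fit_epe()] on each record's profile and appends the fitted
#' parameters, fit score and derived geometry ([shape_metrics()]), yielding
#' the per-fruit record table all cohort analyses consume.
#'
#' @param cohort Tibble from [generate_cohort()] (or any tibble with a
#'   `profile` list-column).
#' @param ... Passed to [fit_epe()].
#' @return The input with fitted columns appended: parameters `a`..`c3`,
#'   `rss`, `rmse_adj`, `converged`, and the fit-derived geometry `v_pred`,
#'   `s`, `l`, `w`, `w_over_l`.
#' @export
fit_cohort <- function(cohort, ...) {
  fits <- purrr::map(cohort$profile, fit_epe, ...)
  fit_tbl <- purrr::map_dfr(fits, function(f) {
    g <- if (epe_params_valid(f$params)) {
      shape_metrics(f$params)
    } else {
      tibble::tibble(v_pred = NA_real_, s = NA_real_, l = NA_real_,
                     w = NA_real_, w_over_l = NA_real_)
    }
    tibble::tibble(
      a = f$params$a, b = f$params$b,
      c1 = f$params$c1, c2 = f$params$c2, c3 = f$params$c3,
      rss = f$rss, rmse_adj = f$rmse_adj, converged = f$converged,
      v_pred = g$v_pred, s = g$s, l = g$l, w = g$w, w_over_l = g$w_over_l
    )
  })
  dplyr::bind_cols(cohort, fit_tbl)
}
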