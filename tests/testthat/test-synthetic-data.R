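test_that("parameter draws respect the spec and are reproducible", {
  spec <- cultivar_preset("cherry", seed = 77)
  d1 <- withr::with_seed(77, sample_epe_params(spec, 50))
  d2 <- withr::with_seed(77, sample_epe_params(spec, 50))
  expect_identical(d1, d2)
  expect_true(all(d1$a >= spec$a_range[1] & d1$a <= spec$a_range[2]))
  expect_true(all(d1$b >= spec$b_range[1] & d1$b <= spec$b_range[2]))
  # zero shape sds give pure spheroids
  sph <- cohort_spec("x", 5, c(1, 1.2), c(1.3, 1.5),
                     c1_sd = 0, c2_sd = 0, c3_sd = 0, seed = 1)
  d3 <- withr::with_seed(1, sample_epe_params(sph, 5))
  expect_true(all(d3$c1 == 0 & d3$c2 == 0 & d3$c3 == 0))
})

test_that("cultivar presets bracket the reported cohort statistics", {
  for (cv in c("cherry", "qianxi", "truss")) {
    spec <- cultivar_preset(cv, seed = 99)
    pars <- withr::with_seed(99, sample_epe_params(spec, spec$n_fruits))
    wl <- purrr::map_dbl(seq_len(nrow(pars)), function(i) {
      lw <- length_width(epe_params(pars$a[i], pars$b[i], pars$c1[i],
                                    pars$c2[i], pars$c3[i]))
      lw[["w"]] / lw[["l"]]
    })
    target <- c(cherry = 0.90, qianxi = 0.89, truss = 0.97)[[cv]]
    expect_gt(median(wl), target - 0.05)
    expect_lt(median(wl), target + 0.05)
  }
  expect_equal(cultivar_preset("cherry")$n_fruits, 297L)
  expect_equal(cultivar_preset("qianxi")$n_fruits, 320L)
  expect_equal(cultivar_preset("truss")$n_fruits, 300L)
})

test_that("volume measurement simulation rounds and floors correctly", {
  expect_equal(withr::with_seed(1, simulate_v_obs(15.34, 0, 1)), 15)
  expect_equal(withr::with_seed(1, simulate_v_obs(7.2, 0, 2)), 8)
  # flooring at one graduation
  expect_equal(withr::with_seed(1, simulate_v_obs(0.2, 0, 1)), 1)
  expect_error(simulate_v_obs(-3), "positive")
  # noise magnitude check before rounding dominates
  set.seed(55)
  v <- simulate_v_obs(rep(1000, 1e4), 0.02, 1e-6)
  expect_equal(sd(v / 1000 - 1), 0.02, tolerance = 0.1)
})

test_that("noisy profile generation degrades gracefully with noise", {
  p <- epe_params(1.4, 1.6, 0.1, -0.05, 0.02)
  # zero noise returns the analytic curve itself
  expect_identical(generate_profile(p, 500, 0), sample_curve(p, 500))
  set.seed(3)
  noisy <- generate_profile(p, 1000, 0.01)
  expect_s3_class(noisy, "fruit_profile")
  expect_lt(ovogeom:::spacing_ratio(noisy), 1.1)
  expect_equal(nrow(noisy), 1000)
  # displacement from the clean curve is on the noise scale
  clean <- sample_curve(p, 1000)
  dmax <- max(abs(sqrt(noisy$x^2 + noisy$y^2) - sqrt(clean$x^2 + clean$y^2)))
  expect_lt(dmax, 0.15)
})

test_that("rendered silhouettes have the right size and margins", {
  mask <- render_image(epe_params(1, 1))
  # 2 cm sphere at 600 dpi: diameter ~ 472 px
  expect_equal(sum(apply(mask, 1, any)), 472, tolerance = 0.01)
  expect_equal(sum(apply(mask, 2, any)), 472, tolerance = 0.01)
  # margins on all four sides
  expect_false(any(mask[1:10, ]) || any(mask[, 1:10]))
  nr <- nrow(mask)
  nc <- ncol(mask)
  expect_false(any(mask[(nr - 9):nr, ]) || any(mask[, (nc - 9):nc]))
  expect_error(render_image(epe_params(1, 1), max_pixels = 1000), "budget")
})

test_that("cohort generation is deterministic and round-trips volumes", {
  spec <- cultivar_preset("cherry", n_fruits = 6, seed = 123,
                          radial_noise_frac = 0)
  c1 <- generate_cohort(spec, n_points = 400)
  c2 <- generate_cohort(spec, n_points = 400)
  expect_identical(dplyr::select(c1, -"profile"),
                   dplyr::select(c2, -"profile"))
  expect_equal(c1$profile[[1]]$x, c2$profile[[1]]$x)
  # noiseless fits recover the generating volume
  fits <- fit_cohort(c1)
  expect_lt(max(abs(fits$v_pred / fits$v_true - 1)), 0.005)
  # written bundles are byte-stable
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, n_points = 400, dir = d1)
  generate_cohort(spec, n_points = 400, dir = d2)
  f1 <- readLines(file.path(d1, "manifest.csv"))
  expect_identical(f1, readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, "cherry_0001.csv")),
                   readLines(file.path(d2, "cherry_0001.csv")))
})
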