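test_that("regression matches the normal-equations oracle exactly", {
  d <- tibble::tibble(x = c(1, 2.5, 3, 4.2, 5.5),
                      y = c(2.1, 4.4, 6.6, 8.1, 11.3))
  got <- ols_with_ci(d, x, y)
  want <- ols_oracle(d$x, d$y)
  expect_equal(got$slope, want$slope, tolerance = 1e-12)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-12)
  expect_equal(c(got$slope_ci_low, got$slope_ci_high), want$ci,
               tolerance = 1e-12)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-12)
  # exact line: slope 2, r^2 = 1, degenerate CI
  ex <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit <- ols_with_ci(ex, x, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope_ci_low, fit$slope_ci_high)
  expect_error(ols_with_ci(ex[1:2, ], x, y), "3")
  expect_error(ols_with_ci(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               "variance")
  expect_error(
    ols_with_ci(tibble::tibble(x = c(-1, 1, 2), y = 1:3), x, y,
                scale = "log10"),
    "positive"
  )
})

test_that("slopes and r-squared do not depend on the log base", {
  set.seed(5)
  d <- tibble::tibble(x = exp(runif(40, 0, 3)))
  d$y <- d$x^0.7 * exp(rnorm(40, 0, 0.05))
  f10 <- ols_with_ci(d, x, y, scale = "log10")
  fe <- ols_oracle(log(d$x), log(d$y))
  expect_equal(f10$slope, fe$slope, tolerance = 1e-12)
  expect_equal(c(f10$slope_ci_low, f10$slope_ci_high), fe$ci,
               tolerance = 1e-12)
  expect_equal(f10$r_squared, fe$r_squared, tolerance = 1e-12)
})

test_that("slope CI has near-nominal coverage", {
  set.seed(17)
  hits <- 0L
  for (r in 1:400) {
    x <- runif(100, 0, 1)
    y <- x + rnorm(100, 0, 0.1)
    f <- ols_with_ci(tibble::tibble(x = x, y = y), x, y)
    hits <- hits + (f$slope_ci_low <= 1 && 1 <= f$slope_ci_high)
  }
  expect_gt(hits / 400, 0.92)
  expect_lt(hits / 400, 0.98)
})

test_that("revolution verdicts behave under agreement and bias", {
  set.seed(13)
  v <- runif(300, 10, 24)
  ok <- revolution_test(tibble::tibble(v_pred = v,
                                       v_obs = v * (1 + rnorm(300, 0, 0.02))))
  expect_true(ok$verdict_strict)
  # systematic 1.5x disagreement is rejected by both verdicts
  bad <- revolution_test(tibble::tibble(v_pred = v, v_obs = 1.5 * v))
  expect_false(bad$verdict_strict)
  expect_false(bad$verdict_band)
  # a tight interval near but off 1 passes only the banded verdict
  v2 <- runif(2000, 5, 30)
  shrunk <- revolution_test(
    tibble::tibble(v_pred = v2, v_obs = v2 / 0.95 * (1 + rnorm(2000, 0, 0.01)))
  )
  expect_false(shrunk$verdict_strict)
  expect_true(shrunk$verdict_band)
  expect_error(revolution_test(tibble::tibble(v_pred = 1:2, v_obs = 1:2)),
               "3")
})

test_that("the attenuation-prone direction is available for comparison", {
  set.seed(19)
  v <- runif(3000, 10, 24)
  d <- tibble::tibble(v_pred = v, v_obs = v * (1 + rnorm(3000, 0, 0.05)))
  att <- revolution_test(d, direction = "pred_on_obs")
  # regressing on the noisy measurement attenuates the slope below 1
  expect_lt(att$slope_ci_high, 1)
  expect_gt(revolution_test(d)$slope_ci_high, 1)
})

test_that("relative-error summaries are exact on constructed inputs", {
  v <- runif(50, 5, 30)
  expect_equal(
    relative_error_summary(tibble::tibble(v_pred = v, v_obs = v))$median_pct,
    0
  )
  expect_equal(
    relative_error_summary(
      tibble::tibble(v_pred = 1.05 * v, v_obs = v)
    )$median_pct,
    5,
    tolerance = 1e-9
  )
  # 2% multiplicative noise -> median |error| near 0.675 * 2%
  set.seed(29)
  vo <- v * (1 + rnorm(length(v) * 200, 0, 0.02))
  vv <- rep(v, 200)
  med <- relative_error_summary(tibble::tibble(v_pred = vv, v_obs = vo))
  expect_equal(med$median_pct, 100 * 0.02 * qnorm(0.75) / 1, # half-normal median
               tolerance = 0.15)
  expect_error(relative_error_summary(tibble::tibble(v_pred = numeric(),
                                                     v_obs = numeric())),
               "records")
})

test_that("allometric exponents reduce to dimensional-analysis values", {
  # isometric family: one shape at 30 sizes
  p <- epe_params(1.3, 1.5, 0.07, -0.02, 0.01)
  ks <- seq(0.5, 2, length.out = 30)
  fam <- purrr::map_dfr(ks, function(k) {
    shape_metrics(epe_params(k * p$a, k * p$b, p$c1, p$c2, p$c3))
  })
  fam$v_obs <- fam$v_pred
  fits <- allometric_fits(fam)
  expect_equal(fits$slope[fits$relation == "s_vs_v_obs"], 2 / 3,
               tolerance = 1e-10)
  expect_equal(fits$slope[fits$relation == "v_pred_vs_lw2"], 1,
               tolerance = 1e-10)
  expect_equal(fits$slope[fits$relation == "s_vs_lw2"], 2 / 3,
               tolerance = 1e-10)
  # without observed volumes only the two geometric fits remain
  fits2 <- allometric_fits(dplyr::select(fam, -"v_obs"))
  expect_equal(nrow(fits2), 2)
  expect_error(allometric_fits(fam[0, ]), "3")
})

test_that("group comparisons separate distinct groups and join equal ones", {
  set.seed(37)
  d <- tibble::tibble(
    cultivar = rep(c("g1", "g2"), each = 50),
    y = c(rnorm(50, 10, 1), rnorm(50, 20, 1))
  )
  gc <- group_compare(d, y)
  expect_lt(glance(gc)$p_value, 1e-10)
  expect_equal(sort(gc$groups$letter), c("a", "b"))
  # literally identical samples give a zero mean difference and one letter
  # (the stochastic null rate is exercised in the sweep below)
  same <- tibble::tibble(
    cultivar = rep(c("g1", "g2"), each = 60),
    y = rep(rnorm(60), 2)
  )
  gs <- group_compare(same, y)
  expect_equal(gs$groups$letter, c("a", "a"))
  # CV of a constant group is zero
  cst <- tibble::tibble(cultivar = rep(c("g1", "g2"), each = 10),
                        y = rep(c(5, 7), each = 10))
  expect_equal(group_compare(cst, y)$groups$cv_pct, c(0, 0))
  expect_error(group_compare(tibble::tibble(cultivar = "g1", y = 1), y),
               "2 groups")
})

test_that("null group comparisons share letters at close to the nominal rate", {
  set.seed(41)
  shared <- 0L
  for (r in 1:200) {
    d <- tibble::tibble(cultivar = rep(c("g1", "g2", "g3"), each = 25),
                        y = rnorm(75))
    g <- group_compare(d, y)
    shared <- shared + all(g$groups$letter == g$groups$letter[1])
  }
  expect_gt(shared / 200, 0.88)
})
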