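test_that("relative error and absolute error behave on exact constructions", {
  d <- tibble::tibble(m = c(10, 20, 40), pmfi_fr_total = c(10, 20, 40))
  b <- bias_inaccuracy(d, m)
  expect_equal(b$mean_rme, 0)
  expect_equal(b$mean_rmae, 0)

  d2 <- tibble::tibble(m = c(5, 10, 20), pmfi_fr_total = c(10, 20, 40))
  b2 <- bias_inaccuracy(d2, m)
  expect_equal(b2$mean_rme, -50)
  expect_equal(b2$mean_rmae, 50)
  expect_equal(b2$n, 3)
})

test_that("inaccuracy dominates bias and both are scale-invariant", {
  for (seed in 1:5) {
    d <- withr::with_seed(seed, tibble::tibble(
      m = stats::rlnorm(30, 3, 0.5),
      pmfi_fr_total = stats::rlnorm(30, 3.2, 0.5)
    ))
    b <- bias_inaccuracy(d, m)
    expect_gte(b$mean_rmae, abs(b$mean_rme))
    b_scaled <- bias_inaccuracy(
      dplyr::mutate(d, m = 3 * m, pmfi_fr_total = 3 * pmfi_fr_total), m
    )
    expect_equal(b_scaled$mean_rme, b$mean_rme)
    expect_equal(b_scaled$mean_rmae, b$mean_rmae)
  }
})

test_that("missing pairs are dropped per estimator, not listwise", {
  d <- tibble::tibble(
    a = c(10, NA, 30, 40), b = c(NA, 2, 3, 4),
    pmfi_fr_total = c(10, 20, 30, NA)
  )
  b <- bias_inaccuracy(d, c(a, b))
  expect_equal(b$n, c(2L, 2L))
})

test_that("a noiseless proportional law is fitted exactly through the origin", {
  d <- tibble::tibble(x = seq(2, 40, by = 2), pmfi_fr_total = 2 * seq(2, 40, by = 2))
  m <- fit_origin_regression(d, "x")
  expect_equal(m$slope, 2)
  expect_equal(m$r2_adj, 1)
  expect_length(m$removed_outliers, 0)
  expect_equal(m$n, 20)
})

test_that("gross outliers are removed by studentized residual, largest first", {
  y <- 2 * (1:20)
  y[10] <- y[10] + 60
  d <- tibble::tibble(case = letters[1:20], x = 1:20, pmfi_fr_total = y)
  m <- fit_origin_regression(d, "x", case_id = "case")
  expect_equal(m$removed_outliers, "j")
  expect_equal(m$slope, 2, tolerance = 1e-6)
  expect_equal(m$n, 19)
  # never more than max_outliers, even with several gross points
  y2 <- 2 * (1:20)
  y2[c(3, 9, 15)] <- y2[c(3, 9, 15)] + c(70, 80, 90)
  d2 <- tibble::tibble(x = 1:20, pmfi_fr_total = y2)
  m2 <- fit_origin_regression(d2, "x", max_outliers = 2)
  expect_length(m2$removed_outliers, 2)
})

test_that("through-origin fits are scale-equivariant in the response", {
  d <- withr::with_seed(2, tibble::tibble(
    x = stats::runif(25, 5, 60)
  ))
  d$pmfi_fr_total <- 1.3 * d$x + stats::rnorm(25, sd = 2)
  m1 <- fit_origin_regression(d, "x")
  m10 <- fit_origin_regression(
    dplyr::mutate(d, pmfi_fr_total = 10 * pmfi_fr_total), "x"
  )
  expect_equal(m10$slope, 10 * m1$slope, tolerance = 1e-9)
})

test_that("degenerate and undersized calibration inputs are refused", {
  expect_error(
    fit_origin_regression(
      tibble::tibble(x = rep(0, 12), pmfi_fr_total = 1:12), "x"
    ),
    class = "firerate_error_degenerate"
  )
  expect_error(
    fit_origin_regression(
      tibble::tibble(x = 1:5, pmfi_fr_total = 2 * (1:5)), "x"
    ),
    class = "firerate_error_too_few_cases"
  )
})

test_that("cross-validation is zero on noiseless data and order-invariant", {
  d <- tibble::tibble(case = 1:20, x = 1:20, pmfi_fr_total = 2 * (1:20))
  m <- fit_origin_regression(d, "x", case_id = "case")
  expect_equal(cross_validate(m, seed = 1), 0, tolerance = 1e-10)

  d2 <- withr::with_seed(5, dplyr::mutate(
    d, pmfi_fr_total = pmfi_fr_total + stats::rnorm(20)
  ))
  m_fwd <- fit_origin_regression(d2, "x", case_id = "case")
  m_rev <- fit_origin_regression(d2[20:1, ], "x", case_id = "case")
  expect_equal(cross_validate(m_fwd, seed = 7), cross_validate(m_rev, seed = 7))
  expect_gte(cross_validate(m_fwd, seed = 7), 0)
})

test_that("undersized folds are reduced with a warning", {
  d <- tibble::tibble(x = 1:12, pmfi_fr_total = 2 * (1:12) + 0.1)
  m <- fit_origin_regression(d, "x", min_cases = 5)
  expect_warning(cross_validate(m, folds = 30, seed = 1), regexp = "folds")
})

test_that("best subsets admit only significant sample-size covariates", {
  # with per-term admission at alpha = 0.05, chance admissions occur in a
  # minority of null replicates; a real effect must be found essentially always
  fits <- lapply(1:10, function(r) {
    base <- withr::with_seed(30 + r, tibble::tibble(
      x = stats::runif(60, 5, 60),
      sample_area_ha = stats::runif(60, 80, 2000),
      total_scarred_trees = stats::runif(60, 5, 80),
      scarred_trees_per_100ha = stats::runif(60, 0.5, 20)
    ))
    d_null <- withr::with_seed(130 + r, dplyr::mutate(
      base, pmfi_fr_total = 2 * x + stats::rnorm(60, sd = 3)
    ))
    d_eff <- withr::with_seed(230 + r, dplyr::mutate(
      base,
      pmfi_fr_total = 2 * x - 0.4 * total_scarred_trees +
        stats::rnorm(60, sd = 3)
    ))
    list(
      null = best_subsets_with_sample_size(d_null, "x"),
      eff = best_subsets_with_sample_size(d_eff, "x")
    )
  })
  n_null_clean <- sum(vapply(fits, function(f) {
    length(f$null$covariates) == 0
  }, logical(1)))
  n_eff_found <- sum(vapply(fits, function(f) {
    "total_scarred_trees" %in% f$eff$covariates
  }, logical(1)))
  expect_gte(n_null_clean, 6)
  expect_gte(n_eff_found, 9)
  # slopes are recovered either way
  slopes <- vapply(fits, function(f) f$null$slope, numeric(1))
  expect_equal(mean(slopes), 2, tolerance = 0.05)
})

test_that("tidy and glance expose the calibration in broom form", {
  d <- tibble::tibble(x = 1:15, pmfi_fr_total = 2 * (1:15) + 0.01)
  m <- fit_origin_regression(d, "x")
  td <- generics::tidy(m)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$term, "x")
  gl <- generics::glance(m)
  expect_equal(gl$n, 15)
  expect_equal(gl$slope, td$estimate)
})

test_that("slope uncertainty shrinks as calibration collections grow", {
  cal <- calibration_experiment(plot_config(), n_sites = 48, seed = 7)
  se_at <- vapply(c(12, 24, 48), function(n) {
    m <- fit_origin_regression(cal[seq_len(n), ], "weibull_mean_itfi",
      response = "true_fr", case_id = "site_id", min_cases = 8
    )
    generics::tidy(m)$std.error
  }, numeric(1))
  expect_true(all(diff(se_at) < 0))
})

test_that("calibrated predictions beat the uncorrected estimator against truth", {
  cal <- calibration_experiment(plot_config(), n_sites = 40, seed = 7)
  ok <- stats::complete.cases(cal[, c("weibull_mean_itfi", "true_fr")])
  m <- fit_origin_regression(cal, "weibull_mean_itfi",
    response = "true_fr", case_id = "site_id"
  )
  # the estimator is biased in these conditions, so the slope is far from 1
  expect_gt(abs(m$slope - 1), 0.05)
  pred <- predict_pmfi_fr(cal$weibull_mean_itfi[ok], m)
  rmse_cal <- sqrt(mean((pred - cal$true_fr[ok])^2))
  rmse_naive <- sqrt(mean((cal$weibull_mean_itfi[ok] - cal$true_fr[ok])^2))
  expect_lt(rmse_cal, rmse_naive)
})
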