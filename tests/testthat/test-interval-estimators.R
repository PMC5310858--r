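test_that("the analysis period runs fire-to-fire inside the calendar window", {
  site <- manual_site(list(
    list(first = 1580, last = 1920, scars = c(1590, 1650, 1880, 1910))
  ))
  r <- restrict_analysis_period(
    site,
    analysis_window(1600, 1900, min_samples_accumulated = 0)
  )
  expect_equal(range(r$year), c(1650L, 1880L))
  expect_false(is_short_record(r))
})

test_that("short truncated records are flagged, fire-free windows error", {
  site <- manual_site(list(
    list(first = 1600, last = 1800, scars = c(1700, 1740))
  ))
  r <- restrict_analysis_period(
    site,
    analysis_window(1600, 1900, min_samples_accumulated = 0)
  )
  expect_true(is_short_record(r)) # 40-year span < 50
  expect_error(
    restrict_analysis_period(
      manual_site(list(list(first = 1500, last = 1590, scars = 1550))),
      analysis_window(1600, 1900)
    ),
    class = "firerate_error_no_usable_record"
  )
})

test_that("the sample-depth rule never moves the start year earlier", {
  sim <- simulate_regime(regime_config(
    years = 300, n_trees = 15,
    staggered_ages = TRUE, seed = 4
  ))
  w_on <- analysis_window(1500, 1799, min_samples_accumulated = 10)
  w_off <- analysis_window(1500, 1799, min_samples_accumulated = 0)
  expect_gte(
    min(restrict_analysis_period(sim$site, w_on)$year),
    min(restrict_analysis_period(sim$site, w_off)$year)
  )
})

test_that("composite filters honour the percent-scarred threshold rules", {
  # ten scarred trees alive; 1750 scars only one of them (10%)
  ten <- manual_site(lapply(1:10, function(i) {
    list(first = 1700, last = 1800, scars = if (i == 1) c(1710, 1750) else 1710)
  }))
  expect_true(1750 %in% composite_fire_years(ten, "all"))
  expect_true(1750 %in% composite_fire_years(ten, "pct10")) # 10% >= 10%
  expect_false(1750 %in% composite_fire_years(ten, "pct25"))

  # four scarred trees; 1750 scars one of them (exactly 25%)
  four <- manual_site(lapply(1:4, function(i) {
    list(first = 1700, last = 1800, scars = if (i == 1) c(1710, 1750) else 1710)
  }))
  expect_true(1750 %in% composite_fire_years(four, "pct25", "geq"))
  expect_false(1750 %in% composite_fire_years(four, "pct25", "gt"))
})

test_that("composite lists shrink as the filter threshold rises", {
  for (seed in c(2, 9)) {
    site <- simulate_regime(plot_config(seed = seed))$site
    n_all <- length(composite_fire_years(site, "all"))
    n_10 <- length(composite_fire_years(site, "pct10"))
    n_25 <- length(composite_fire_years(site, "pct25"))
    expect_lte(n_25, n_10)
    expect_lte(n_10, n_all)
  }
})

test_that("fire intervals are successive differences conserving the span", {
  expect_equal(fire_intervals(c(1700, 1710, 1725)), c(10L, 15L))
  expect_equal(mean(fire_intervals(c(1700, 1710, 1725))), 12.5)
  expect_error(fire_intervals(1700),
    class = "firerate_error_insufficient_intervals"
  )
  yrs <- composite_fire_years(simulate_regime(plot_config(seed = 3))$site)
  expect_equal(sum(fire_intervals(yrs)), max(yrs) - min(yrs))
})

test_that("individual-tree intervals average per tree, then across trees", {
  site <- manual_site(list(
    list(first = 1690, last = 1800, scars = c(1700, 1710, 1720)), # MFI 10
    list(first = 1690, last = 1800, scars = c(1700, 1730, 1760)), # MFI 30
    list(first = 1690, last = 1800, scars = 1705) # < 2 scars: excluded
  ))
  it <- itfi(site)
  expect_equal(it$n_trees, 2)
  expect_equal(sort(it$per_tree$mean_interval), c(10, 30))
  expect_equal(it$grand_mean, 20)

  one <- manual_site(list(list(first = 1690, last = 1800,
                               scars = c(1700, 1720, 1760))))
  expect_equal(itfi(one)$grand_mean, 30)

  expect_error(
    itfi(manual_site(list(list(first = 1700, last = 1750, scars = 1710)))),
    class = "firerate_error_insufficient_intervals"
  )
})

test_that("Weibull MLE recovers known parameters and flags degenerate input", {
  x <- withr::with_seed(11, stats::rweibull(5000, shape = 2, scale = 20))
  fit <- fit_weibull(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  expect_lt(abs(fit$scale - 20) / 20, 0.05)

  expect_false(fit_weibull(c(10, 10, 10, 10))$converged)
  expect_false(fit_weibull(c(5, 9))$converged) # too few
})

test_that("the exponential special case ties the Weibull mean to its scale", {
  ws <- weibull_stats(shape = 1, scale = 37)
  expect_equal(ws$weibull_mean, 37)
  expect_equal(ws$weibull_median, 37 * log(2))
  # median < mean for shapes below ~3.26 (right skew)
  expect_lt(weibull_stats(2, 20)$weibull_median, weibull_stats(2, 20)$weibull_mean)
})

test_that("the estimator suite assembles composite and tree-level measures", {
  site <- manual_site(
    list(list(first = 1690, last = 1730, scars = c(1700, 1710, 1725))),
    area_ha = 200
  )
  suite <- estimator_suite(site)
  expect_equal(suite$mean_cfi_all, 12.5)
  expect_equal(suite$median_cfi_all, 12.5)
  expect_true(is.na(suite$weibull_mean_cfi_all)) # two intervals: no fit
  expect_equal(suite$total_scarred_trees, 1)
  expect_equal(suite$scarred_trees_per_100ha, 0.5)
})

test_that("filtered composite means lengthen and tree means exceed composites", {
  # raising the percent-scarred threshold drops fire years but also shrinks
  # the composite span, so per-site monotonicity can be violated occasionally;
  # the ordering holds in expectation and for the large majority of sites
  ge_with_tol <- function(a, b) a >= b - 1e-9
  sites <- lapply(21:32, function(s) {
    simulate_regime(plot_config(seed = s))$site
  })
  suites <- dplyr::bind_rows(lapply(sites, estimator_suite))
  ok10 <- mean(ge_with_tol(suites$mean_cfi10, suites$mean_cfi_all), na.rm = TRUE)
  ok25 <- mean(ge_with_tol(suites$mean_cfi25, suites$mean_cfi10), na.rm = TRUE)
  okit <- mean(ge_with_tol(suites$mean_itfi, suites$mean_cfi_all), na.rm = TRUE)
  expect_gte(ok10, 0.75)
  expect_gte(ok25, 0.75)
  expect_gte(okit, 0.9)
  expect_gt(mean(suites$mean_cfi10 - suites$mean_cfi_all, na.rm = TRUE), 0)
  expect_gt(mean(suites$mean_cfi25 - suites$mean_cfi10, na.rm = TRUE), 0)
  expect_gt(mean(suites$mean_itfi - suites$mean_cfi_all, na.rm = TRUE), 0)
})
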