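test_that("slope-only prediction is proportional and guards its domain", {
  d <- tibble::tibble(x = seq(5, 60, by = 5), pmfi_fr_total = 1.5 * seq(5, 60, by = 5))
  m <- fit_origin_regression(d, "x")
  expect_equal(predict_pmfi_fr(30, m), 45)
  expect_equal(predict_pmfi_fr(2 * 30, m), 2 * predict_pmfi_fr(30, m))
  expect_error(predict_pmfi_fr(0, m), class = "firerate_error_bad_input")
  expect_true(is.na(predict_pmfi_fr(c(10, NA), m)[2]))
})

test_that("covariate models predict from data frames", {
  base <- withr::with_seed(41, tibble::tibble(
    x = stats::runif(40, 5, 60),
    sample_area_ha = stats::runif(40, 80, 2000),
    total_scarred_trees = stats::runif(40, 5, 80),
    scarred_trees_per_100ha = stats::runif(40, 0.5, 20)
  ))
  d <- dplyr::mutate(base,
    pmfi_fr_total = 1.2 * x - 0.5 * total_scarred_trees +
      withr::with_seed(42, stats::rnorm(40, sd = 1))
  )
  m <- best_subsets_with_sample_size(d, "x")
  if (length(m$covariates) > 0) {
    expect_error(predict_pmfi_fr(30, m), class = "firerate_error_bad_input")
    newdata <- tibble::tibble(x = 30, total_scarred_trees = 10,
                              sample_area_ha = 500,
                              scarred_trees_per_100ha = 2)
    pred <- predict_pmfi_fr(newdata, m)
    manual <- sum(m$coefs * vapply(names(m$coefs), function(nm) {
      newdata[[if (nm == m$predictor) "x" else nm]][[1]]
    }, numeric(1)))
    expect_equal(pred, manual)
  } else {
    expect_equal(predict_pmfi_fr(30, m), m$slope * 30)
  }
})

test_that("group summaries report the standard descriptive block", {
  d <- tibble::tibble(
    pmfi_fr = c(10, 20, 30, 40, 55, 80, 12, 18),
    state = c(rep("AZ", 4), rep("CO", 3), "NM")
  )
  overall <- summarize_rates(d)
  expect_equal(overall$n, 8)
  expect_equal(overall$mean, mean(d$pmfi_fr))
  expect_equal(overall$median, stats::median(d$pmfi_fr))
  expect_equal(overall$cv_percent, 100 * stats::sd(d$pmfi_fr) / mean(d$pmfi_fr))
  expect_true(overall$min <= overall$q1 && overall$q1 <= overall$median &&
    overall$median <= overall$q3 && overall$q3 <= overall$max)

  by_state <- summarize_rates(d, group_by = "state")
  expect_equal(sum(by_state$n), overall$n)
  # single-member groups: no spread statistics
  nm <- by_state[by_state$state == "NM", ]
  expect_equal(nm$mean, nm$median)
  expect_equal(nm$min, nm$max)
  expect_true(is.na(nm$sd))
  # permutation invariance
  shuffled <- summarize_rates(d[sample.int(8), ], group_by = "state")
  expect_equal(
    dplyr::arrange(by_state, state),
    dplyr::arrange(shuffled, state)
  )
})

test_that("the median interval covers the true median on well-behaved samples", {
  x <- withr::with_seed(13, stats::rlnorm(150, log(30), 0.5))
  s <- summarize_rates(tibble::tibble(pmfi_fr = x))
  expect_lt(s$ci95_median_lo, 30)
  expect_gt(s$ci95_median_hi, 30)
  expect_lt(s$ci95_mean_lo, s$mean)
  expect_gt(s$ci95_mean_hi, s$mean)
})

test_that("forest-type comparison runs a Welch test", {
  d <- withr::with_seed(14, tibble::tibble(
    pmfi_fr = c(stats::rlnorm(30, log(35), 0.4), stats::rlnorm(25, log(36), 0.6)),
    forest_type = c(rep("dry_pine", 30), rep("dry_mixed_conifer", 25))
  ))
  cmp <- compare_groups(d)
  expect_true(is.finite(cmp$statistic))
  expect_true(cmp$p.value > 0 && cmp$p.value <= 1)
  expect_error(
    compare_groups(dplyr::mutate(d, forest_type = "dry_pine")),
    class = "firerate_error_bad_input"
  )
})

test_that("histograms bin from zero and report strict exceedance", {
  h <- rate_histogram(c(10, 20, 30, 40), bin_width = 15, thresholds = 25)
  expect_equal(h$thresholds$pct_exceeding, 50)
  expect_equal(h$bins$lower[1], 0)
  expect_equal(h$bins$pct_exceeding_lower[1], 100) # all positive values
  expect_equal(sum(h$bins$count), 4)
  expect_equal(h$bins$count[1:3], c(1L, 1L, 2L)) # [0,15) [15,30) [30,45)
  expect_error(rate_histogram(c(-1, 5)), class = "firerate_error_bad_input")
})

test_that("beginning years proxy old-forest status", {
  expect_equal(
    as.character(old_forest_proxy(c(1650, 1749, 1800, NA))),
    c("ge200", "ge150", "younger", NA)
  )
  expect_equal(as.character(old_forest_proxy(1699)), "ge200")
  expect_equal(as.character(old_forest_proxy(1700)), "ge150")
})

test_that("the low-severity classifier uses strict printed thresholds", {
  expect_true(low_severity_classifier(100, 50, 20))
  expect_false(low_severity_classifier(200, 50, 20))
  expect_false(low_severity_classifier(178, 29.2, 46.9)) # boundary excluded
  expect_equal(
    low_severity_classifier(c(100, 200), c(50, 50), c(20, 20)),
    c(TRUE, FALSE)
  )
})

test_that("area weighting pools landscapes by hectares, not by case", {
  expect_equal(area_weighted_percentage(100, 50), 50)
  tab <- dry_forest_landscapes()
  pct <- area_weighted_percentage(tab$area_ha, tab$fitting_ha)
  expect_gte(pct, min(tab$pct_low_severity))
  expect_lte(pct, max(tab$pct_low_severity))
  # weighting differs from the unweighted mean when areas differ
  expect_false(isTRUE(all.equal(pct, mean(tab$pct_low_severity), tolerance = 1e-6)))
  expect_error(area_weighted_percentage(c(0, 0), c(0, 0)),
    class = "firerate_error_bad_input"
  )
  expect_error(area_weighted_percentage(100, 150),
    class = "firerate_error_bad_input"
  )
})

test_that("class shares compose multiplicatively across nested areas", {
  expect_equal(frequent_fire_share(41, 34), 13.94)
  expect_equal(frequent_fire_share(100, 34), 34)
  expect_equal(frequent_fire_share(0, 34), 0)
})
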