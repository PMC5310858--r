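#' Composite fire years
#'
#' Pools fire-scar years across all series in a site into the classic
#' composite chronology, optionally filtered to "larger" fires that scarred at
#' least 10% or 25% of the scarred samples alive in that year. The filter
#' denominator counts series that are alive in the year and carry at least one
#' scar during the analysis period (scarred samples); an unfiltered composite
#' keeps every year with one or more scars.
#'
#' The percent-scarred comparison defaults to `>=` (a fire on exactly 25% of
#' scarred samples qualifies under `pct25`); set `threshold_rule = "gt"` for
#' the strict variant.
#'
#' @param site A (typically restricted) [fhx_site()].
#' @param filter `"all"`, `"pct10"` or `"pct25"`.
#' @param threshold_rule `">="` semantics (`"geq"`, default) or strict
#'   (`"gt"`).
#' @return Sorted integer vector of composite fire years (possibly empty).
#' @export
composite_fire_years <- function(site, filter = c("all", "pct10", "pct25"),
                                 threshold_rule = c("geq", "gt")) {
  filter <- match.arg(filter)
  threshold_rule <- match.arg(threshold_rule)
  spans <- series_spans(site)
  scarred <- spans[spans$n_scars > 0, ]
  counts <- site |>
    dplyr::filter(is_scar_code(.data$code)) |>
    dplyr::summarise(n_scarred = dplyr::n_distinct(.data$series),
                     .by = "year") |>
    dplyr::arrange(.data$year)
  if (nrow(counts) == 0 || filter == "all") {
    return(counts$year)
  }
  threshold <- c(pct10 = 0.10, pct25 = 0.25)[[filter]]
  denom <- vapply(counts$year, function(y) {
    sum(scarred$first_year <= y & scarred$last_year >= y)
  }, integer(1))
  frac <- counts$n_scarred / denom
  keep <- if (threshold_rule == "geq") frac >= threshold else frac > threshold
  counts$year[keep & counts$n_scarred >= 1]
}

#' Intervals between composite fire years
#'
#' @param years Sorted fire-year vector (at least two years).
#' @return Integer vector of successive differences, all `>= 1`.
#' @export
fire_intervals <- function(years) {
  years <- sort(unique(as.integer(years)))
  if (length(years) < 2) {
    rlang::abort("insufficient intervals: need at least two fire years",
      class = "firerate_error_insufficient_intervals"
    )
  }
  diff(years)
}

#' Individual-tree fire intervals (ITFI)
#'
#' Computes, for every series with at least two scars, that tree's mean
#' inter-scar interval, then the unweighted grand mean and grand median across
#' qualifying trees. Trees with fewer than two scars contribute nothing.
#'
#' @param site A (typically restricted) [fhx_site()].
#' @return A list of class `itfi_summary`: `per_tree` (tibble with `series`,
#'   `n_scars`, `mean_interval`), `grand_mean`, `grand_median`, `n_trees`, and
#'   `intervals` (all individual-tree intervals pooled, used for the Weibull
#'   ITFI measures).
#' @export
itfi <- function(site) {
  per_tree <- site |>
    dplyr::filter(is_scar_code(.data$code)) |>
    dplyr::summarise(
      n_scars = dplyr::n_distinct(.data$year),
      mean_interval = if (dplyr::n_distinct(.data$year) >= 2) {
        mean(diff(sort(unique(.data$year))))
      } else {
        NA_real_
      },
      intervals = list(if (dplyr::n_distinct(.data$year) >= 2) {
        diff(sort(unique(.data$year)))
      } else {
        integer(0)
      }),
      .by = "series"
    ) |>
    dplyr::filter(.data$n_scars >= 2)
  if (nrow(per_tree) == 0) {
    rlang::abort("insufficient intervals: no series with two or more scars",
      class = "firerate_error_insufficient_intervals"
    )
  }
  structure(
    list(
      per_tree = dplyr::select(per_tree, "series", "n_scars", "mean_interval"),
      grand_mean = mean(per_tree$mean_interval),
      grand_median = stats::median(per_tree$mean_interval),
      n_trees = nrow(per_tree),
      intervals = unlist(per_tree$intervals)
    ),
    class = "itfi_summary"
  )
}

#' @export
print.itfi_summary <- function(x, ...) {
  cat(sprintf(
    "<itfi_summary> %d qualifying trees; grand mean %.2f yr, grand median %.2f yr\n",
    x$n_trees, x$grand_mean, x$grand_median
  ))
  invisible(x)
}

#' Theoretical Weibull mean and median
#'
#' For shape `k` and scale `b` (the 63rd percentile of the distribution), the
#' mean is `b * gamma(1 + 1/k)` and the median `b * log(2)^(1/k)`; at `k = 1`
#' the mean equals the scale.
#'
#' @param shape,scale Weibull parameters (`> 0`).
#' @return A list with `weibull_mean` and `weibull_median`.
#' @export
weibull_stats <- function(shape, scale) {
  list(
    weibull_mean = scale * gamma(1 + 1 / shape),
    weibull_median = scale * log(2)^(1 / shape)
  )
}

#' Two-parameter Weibull fit to fire intervals
#'
#' Maximum-likelihood fit of the two-parameter Weibull (shift fixed at zero)
#' to a set of fire intervals. Fewer than three intervals, zero-variance
#' (degenerate) interval sets, or non-convergence are reported as a missing
#' fit rather than an error, mirroring the variable availability of Weibull
#' estimators across real sites.
#'
#' @param intervals Positive interval lengths in years.
#' @return A one-row tibble: `shape`, `scale`, `weibull_mean`,
#'   `weibull_median`, `n`, `converged`.
#' @export
fit_weibull <- function(intervals) {
  intervals <- as.numeric(intervals)
  na_fit <- tibble::tibble(
    shape = NA_real_, scale = NA_real_, weibull_mean = NA_real_,
    weibull_median = NA_real_, n = length(intervals), converged = FALSE
  )
  if (length(intervals) < 3 || any(intervals <= 0) ||
    stats::sd(intervals) == 0) {
    return(na_fit)
  }
  fit <- tryCatch(
    suppressWarnings(fitdistrplus::fitdist(intervals, "weibull")),
    error = function(e) NULL
  )
  if (is.null(fit) || anyNA(fit$estimate)) {
    return(na_fit)
  }
  k <- unname(fit$estimate["shape"])
  b <- unname(fit$estimate["scale"])
  ws <- weibull_stats(k, b)
  tibble::tibble(
    shape = k, scale = b, weibull_mean = ws$weibull_mean,
    weibull_median = ws$weibull_median, n = length(intervals),
    converged = TRUE
  )
}

measure_block <- function(intervals, suffix) {
  out <- list()
  out[[paste0("mean_", suffix)]] <- if (length(intervals) >= 1) {
    mean(intervals)
  } else {
    NA_real_
  }
  out[[paste0("median_", suffix)]] <- if (length(intervals) >= 1) {
    stats::median(intervals)
  } else {
    NA_real_
  }
  wb <- fit_weibull(intervals)
  out[[paste0("weibull_scale_", suffix)]] <- wb$scale
  out[[paste0("weibull_mean_", suffix)]] <- wb$weibull_mean
  out[[paste0("weibull_median_", suffix)]] <- wb$weibull_median
  out
}

#' Per-site estimator suite
#'
#' Assembles the 20 CFI/ITFI estimator values for a site: mean and median of
#' raw intervals plus Weibull scale/mean/median of the fitted distribution,
#' for the unfiltered composite, the 10%- and 25%-scarred composites, and the
#' individual-tree family (whose Weibull measures are fitted to the pooled
#' individual-tree intervals), together with the sample-size covariates used
#' by the best-subset calibration models. Estimators that cannot be computed
#' (too few intervals, degenerate fits) are missing, not errors.
#'
#' @param site A [fhx_site()].
#' @param window Optional [analysis_window()]; when supplied the site is
#'   restricted first.
#' @param threshold_rule Percent-scarred comparison rule, see
#'   [composite_fire_years()].
#' @return A one-row tibble: `site_id`, the 20 estimator columns,
#'   `sample_area_ha`, `total_scarred_trees`, `scarred_trees_per_100ha`.
#' @export
estimator_suite <- function(site, window = NULL,
                            threshold_rule = c("geq", "gt")) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.null(window)) {
    site <- restrict_analysis_period(site, window)
  }
  meta <- fhx_meta(site)
  vals <- list(site_id = meta$site_id)
  fams <- c(all = "cfi_all", pct10 = "cfi10", pct25 = "cfi25")
  for (mode in names(fams)) {
    yrs <- composite_fire_years(site, filter = mode,
                                threshold_rule = threshold_rule)
    ints <- if (length(yrs) >= 2) diff(yrs) else numeric(0)
    vals <- c(vals, measure_block(ints, fams[[mode]]))
  }
  it <- tryCatch(itfi(site), firerate_error_insufficient_intervals =
                   function(e) NULL)
  if (is.null(it)) {
    vals <- c(vals, measure_block(numeric(0), "itfi"))
  } else {
    wb <- fit_weibull(it$intervals)
    vals <- c(vals, list(
      mean_itfi = it$grand_mean,
      median_itfi = it$grand_median,
      weibull_scale_itfi = wb$scale,
      weibull_mean_itfi = wb$weibull_mean,
      weibull_median_itfi = wb$weibull_median
    ))
  }
  spans <- series_spans(site)
  tst <- sum(spans$n_scars > 0)
  vals$sample_area_ha <- meta$area_ha
  vals$total_scarred_trees <- tst
  vals$scarred_trees_per_100ha <- if (!is.na(meta$area_ha)) {
    100 * tst / meta$area_ha
  } else {
    NA_real_
  }
  tibble::as_tibble(vals)
}
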