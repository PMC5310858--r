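#' Group summaries of historical fire rates
#'
#' Computes the descriptive block reported for site collections: n, mean with
#' 95% t-interval, standard deviation, coefficient of variation (percent,
#' sample sd), minimum, quartiles, median with a distribution-free 95%
#' interval (order-statistic/binomial, interpolated), and maximum. Groups with
#' a single member report `sd`, `cv_percent` and intervals as missing.
#'
#' @param data A data frame of per-site predictions.
#' @param value Name of the rate column in years (default `"pmfi_fr"`).
#' @param group_by Optional character vector of grouping columns; `NULL`
#'   summarizes the whole collection as group `"overall"`.
#' @return A tibble with one row per group.
#' @export
summarize_rates <- function(data, value = "pmfi_fr", group_by = NULL) {
  if (!value %in% names(data)) {
    rlang::abort(sprintf("column '%s' not found", value),
      class = "firerate_error_schema"
    )
  }
  df <- tibble::as_tibble(data)
  df <- df[!is.na(df[[value]]), , drop = FALSE]
  if (is.null(group_by)) {
    df$.group <- "overall"
    group_by <- ".group"
  }
  dropped <- df |>
    dplyr::summarise(n = dplyr::n(), .by = dplyr::all_of(group_by)) |>
    dplyr::filter(.data$n == 0)
  if (nrow(dropped) > 0) {
    rlang::inform("empty group(s) omitted from summary")
  }
  df |>
    dplyr::summarise(
      summary_stats(.data[[value]]),
      .by = dplyr::all_of(group_by)
    ) |>
    dplyr::rename_with(~ sub("^\\.group$", "group", .x))
}

summary_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) stats::sd(x) else NA_real_
  ci <- if (n > 1) {
    m + stats::qt(c(0.025, 0.975), n - 1) * s / sqrt(n)
  } else {
    c(NA_real_, NA_real_)
  }
  mci <- median_ci(x)
  tibble::tibble(
    n = n, mean = m, ci95_mean_lo = ci[1], ci95_mean_hi = ci[2],
    sd = s, cv_percent = 100 * s / m,
    min = min(x), q1 = unname(stats::quantile(x, 0.25)),
    median = stats::median(x),
    ci95_median_lo = mci[1], ci95_median_hi = mci[2],
    q3 = unname(stats::quantile(x, 0.75)), max = max(x)
  )
}

# Distribution-free CI for the median: conservative order-statistic
# (binomial) interval, linearly interpolated toward the next-inner order
# statistics to approximate nominal 95% coverage.
median_ci <- function(x, conf = 0.95) {
  n <- length(x)
  if (n < 6) {
    return(c(NA_real_, NA_real_))
  }
  alpha <- (1 - conf) / 2
  xs <- sort(x)
  k <- stats::qbinom(alpha, n, 0.5) # P(X < k) <= alpha < P(X <= k)
  if (k < 1) k <- 1
  p_outer <- stats::pbinom(k - 1, n, 0.5)
  p_inner <- stats::pbinom(k, n, 0.5)
  lambda <- if (p_inner > p_outer) {
    (alpha - p_outer) / (p_inner - p_outer)
  } else {
    0
  }
  lo <- (1 - lambda) * xs[k] + lambda * xs[min(k + 1, n)]
  hi <- (1 - lambda) * xs[n - k + 1] + lambda * xs[max(n - k, 1)]
  c(lo, hi)
}

#' Welch comparison of mean rates between two groups
#'
#' @param data A data frame of per-site predictions.
#' @param value Rate column name.
#' @param group Grouping column name; must have exactly two non-missing
#'   levels.
#' @return A one-row tibble: `estimate1`, `estimate2`, `statistic`, `df`,
#'   `p.value`.
#' @export
compare_groups <- function(data, value = "pmfi_fr", group = "forest_type") {
  g <- data[[group]]
  v <- data[[value]]
  ok <- !is.na(g) & !is.na(v)
  levels <- unique(g[ok])
  if (length(levels) != 2) {
    rlang::abort("group column must have exactly two levels",
      class = "firerate_error_bad_input"
    )
  }
  tt <- stats::t.test(v[ok & g == levels[1]], v[ok & g == levels[2]])
  tibble::tibble(
    group1 = as.character(levels[1]), group2 = as.character(levels[2]),
    estimate1 = unname(tt$estimate[1]), estimate2 = unname(tt$estimate[2]),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p.value = tt$p.value
  )
}

#' Binned histogram of rates with threshold exceedance
#'
#' Bins positive rate values into fixed-width, half-open bins `[0, w)`,
#' `[w, 2w)`, ... and reports, for each bin lower limit and any extra
#' thresholds, the percentage of the distribution strictly exceeding that
#' limit (so exceedance at 0 is 100% for positive data).
#'
#' @param values Positive rates in years.
#' @param bin_width Bin width in years (default 15).
#' @param thresholds Extra threshold(s) at which to report exceedance
#'   (default 25).
#' @return A list of class `rate_histogram`: `bins` (tibble `lower`, `upper`,
#'   `count`, `pct_exceeding_lower`), `thresholds` (tibble `threshold`,
#'   `pct_exceeding`), `bin_width`, `n`.
#' @export
rate_histogram <- function(values, bin_width = 15, thresholds = 25) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) {
    rlang::abort("rates must be positive", class = "firerate_error_bad_input")
  }
  upper <- bin_width * ceiling(max(values) / bin_width)
  lowers <- seq(0, upper - bin_width, by = bin_width)
  counts <- vapply(lowers, function(lo) {
    sum(values >= lo & values < lo + bin_width)
  }, integer(1))
  exceed <- function(t) 100 * mean(values > t)
  bins <- tibble::tibble(
    lower = lowers, upper = lowers + bin_width, count = counts,
    pct_exceeding_lower = vapply(lowers, exceed, numeric(1))
  )
  thr <- tibble::tibble(
    threshold = thresholds,
    pct_exceeding = vapply(thresholds, exceed, numeric(1))
  )
  structure(
    list(bins = bins, thresholds = thr, bin_width = bin_width,
         n = length(values)),
    class = "rate_histogram"
  )
}

#' @export
print.rate_histogram <- function(x, ...) {
  cat(sprintf("<rate_histogram> %d values, %g-year bins\n", x$n, x$bin_width))
  print(x$bins)
  if (nrow(x$thresholds) > 0) print(x$thresholds)
  invisible(x)
}

#' Old-forest age proxy from analysis beginning year
#'
#' Stands whose analysis record begins before 1700 CE were generally at least
#' 200 years old by 1900, and before 1750 at least 150 years old; later
#' beginning years are classed as younger.
#'
#' @param beginning_year Calendar year(s).
#' @return A factor with levels `ge200`, `ge150`, `younger`.
#' @export
old_forest_proxy <- function(beginning_year) {
  out <- dplyr::case_when(
    is.na(beginning_year) ~ NA_character_,
    beginning_year < 1700 ~ "ge200",
    beginning_year < 1750 ~ "ge150",
    TRUE ~ "younger"
  )
  factor(out, levels = c("ge200", "ge150", "younger"))
}

#' Low-severity fire-regime classifier
#'
#' The calibrated structural model predicts a history of predominantly
#' low-severity fire where historical tree density was below 178 trees/ha,
#' the percentage of large trees above 29.2%, and the percentage of small
#' trees below 46.9% (all strict inequalities).
#'
#' @param tree_density Trees per hectare (non-negative).
#' @param pct_large,pct_small Percentages in \[0, 100\].
#' @return Logical vector.
#' @export
low_severity_classifier <- function(tree_density, pct_large, pct_small) {
  stopifnot(
    all(tree_density >= 0, na.rm = TRUE),
    all(pct_large >= 0 & pct_large <= 100, na.rm = TRUE),
    all(pct_small >= 0 & pct_small <= 100, na.rm = TRUE)
  )
  tree_density < 178 & pct_large > 29.2 & pct_small < 46.9
}

#' Area-weighted percentage of landscapes fitting a model
#'
#' `100 * sum(fitting_ha) / sum(total_ha)` across a set of landscapes; the
#' result always lies between the smallest and largest per-landscape
#' percentage.
#'
#' @param total_ha,fitting_ha Per-landscape total and fitting areas in
#'   hectares (`fitting_ha <= total_ha`).
#' @return The area-weighted percentage.
#' @export
area_weighted_percentage <- function(total_ha, fitting_ha) {
  stopifnot(length(total_ha) == length(fitting_ha))
  if (sum(total_ha) <= 0) {
    rlang::abort("total area must be positive",
      class = "firerate_error_bad_input"
    )
  }
  if (any(fitting_ha > total_ha)) {
    rlang::abort("fitting_ha must not exceed total_ha",
      class = "firerate_error_bad_input"
    )
  }
  100 * sum(fitting_ha) / sum(total_ha)
}

#' Dry-forest landscapes assessed against the low-severity model
#'
#' The eleven western-USA dry-forest landscapes with General Land Office
#' survey or early aerial-photograph reconstructions of historical structure,
#' with total area and the area fitting the low-severity fire model. These
#' published figures are the inputs for [area_weighted_percentage()].
#'
#' @return A tibble with `source`, `location`, `area_ha`, `pct_low_severity`,
#'   `fitting_ha`.
#' @export
dry_forest_landscapes <- function() {
  tibble::tribble(
    ~source, ~location, ~area_ha, ~pct_low_severity, ~fitting_ha,
    "GLO", "Mogollon Plateau, AZ", 405214, 62.4, 252854,
    "GLO", "Black Mesa, AZ", 151080, 12.0, 18130,
    "GLO", "Front Range, CO", 65525, 2.5, 1638,
    "GLO", "Blue Mountains, OR", 304709, 40.3, 122798,
    "GLO", "North-E Cascades, OR", 146555, 32.5, 47630,
    "GLO", "Central-E Cascades, OR", 147502, 10.4, 15340,
    "GLO", "South-E Cascades, OR", 104160, 29.4, 30623,
    "GLO", "Coconino Plateau, AZ", 41214, 58.8, 24234,
    "GLO", "N. Sierra, CA", 115766, 12.6, 14587,
    "GLO", "S. Sierra, CA", 187085, 26.4, 49390,
    "aerial photographs", "E. WA & E. OR", 112115, 21.6, 24200
  )
}

#' Compose a share of old forest with a landscape share
#'
#' Multiplies the percentage of old-forest sites in a rate class by the
#' percentage of the landscape that is old forest with a low-severity fire
#' history, giving the share of the whole dry-forest area in that class
#' (e.g. 41% of 34% is about 14%).
#'
#' @param pct_of_old_forest Percentage of old-forest sites in the class.
#' @param pct_old_forest_area Percentage of the landscape that is old forest.
#' @return Percentage of the whole landscape.
#' @export
frequent_fire_share <- function(pct_of_old_forest, pct_old_forest_area) {
  pct_of_old_forest * pct_old_forest_area / 100
}
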