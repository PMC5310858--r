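#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Fire-history chart for a site
#'
#' The classic fire-demography chart: one horizontal line per series spanning
#' its record, tick marks at fire-scar years, and a rug of composite fire
#' years along the axis.
#'
#' @param site A [fhx_site()].
#' @return A ggplot object.
#' @export
plot_fire_history <- function(site) {
  spans <- series_spans(site)
  spans$series <- factor(spans$series, levels = rev(sort(spans$series)))
  scars <- dplyr::filter(site, is_scar_code(.data$code))
  scars$series <- factor(scars$series, levels = levels(spans$series))
  comp <- tibble::tibble(year = composite_fire_years(site))
  ggplot2::ggplot(spans) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$first_year, xend = .data$last_year,
        y = .data$series, yend = .data$series
      ),
      linewidth = 0.3, colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = scars,
      ggplot2::aes(x = .data$year, y = .data$series),
      shape = 124, size = 3
    ) +
    ggplot2::geom_rug(
      data = comp, ggplot2::aes(x = .data$year),
      sides = "b", length = ggplot2::unit(0.03, "npc")
    ) +
    ggplot2::labs(
      x = "Year CE", y = NULL,
      title = fhx_meta(site)$site_id,
      subtitle = sprintf(
        "%d series, %d composite fire years",
        nrow(spans), nrow(comp)
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_fire_history
#' @param object A [fhx_site()].
#' @param ... Unused.
#' @export
autoplot.fhx_site <- function(object, ...) plot_fire_history(object)

#' Plot a calibration regression
#'
#' Scatter of reference PMFI/FR against the estimator with the fitted
#' through-origin line; removed outliers are marked with open circles.
#'
#' @param object A `fire_calibration` from [fit_origin_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fire_calibration <- function(object, ...) {
  used <- object$data
  p <- ggplot2::ggplot(used, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      intercept = 0, slope = object$slope,
      colour = "firebrick"
    ) +
    ggplot2::labs(
      x = paste0(object$predictor, " (years)"),
      y = paste0(object$response, " (years)"),
      title = sprintf(
        "%s = %.3f x %s", object$response, object$slope,
        object$predictor
      ),
      subtitle = sprintf(
        "n = %d, R2_adj = %.3f, %d outlier(s) removed",
        object$n, object$r2_adj, length(object$removed_outliers)
      )
    ) +
    ggplot2::theme_minimal()
  p
}

#' Plot a binned rate histogram
#'
#' Bars per bin with the percentage of the distribution exceeding each bin's
#' lower limit printed above the bars.
#'
#' @param object A [rate_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_histogram <- function(object, ...) {
  bins <- object$bins
  ggplot2::ggplot(bins, ggplot2::aes(
    x = .data$lower + object$bin_width / 2,
    y = .data$count
  )) +
    ggplot2::geom_col(
      width = object$bin_width * 0.9, fill = "grey35"
    ) +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f%%", .data$pct_exceeding_lower)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = "PMFI/FR (years)", y = "Sites",
      subtitle = sprintf(
        "%d sites; labels: %% of distribution exceeding each bin's lower limit",
        object$n
      )
    ) +
    ggplot2::theme_minimal()
}
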