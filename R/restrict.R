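#' Analysis-period restriction
#'
#' Fire-interval statistics are conventionally computed scar-to-scar: the
#' analysis period runs from the earliest fire to the latest fire inside a
#' fixed calendar window (1600-1900 CE by default), optionally beginning only
#' with the first fire after a minimum sample depth has accumulated, and sites
#' whose restricted span is too short are flagged.
#'
#' @param start_year,end_year Calendar bounds of the admissible window.
#' @param min_record_years Minimum span (last minus first fire year) below
#'   which the restricted site is flagged as a short record. Default 50.
#' @param min_samples_accumulated Sample-depth rule: the analysis may begin
#'   only at the first fire at or after the year in which this many series are
#'   simultaneously alive. `0` disables the rule. Default 10.
#' @return An `analysis_window` list.
#' @export
analysis_window <- function(start_year = 1600, end_year = 1900,
                            min_record_years = 50,
                            min_samples_accumulated = 10) {
  if (end_year <= start_year) {
    rlang::abort("end_year must exceed start_year",
      class = "firerate_error_bad_window"
    )
  }
  structure(
    list(
      start_year = as.integer(start_year), end_year = as.integer(end_year),
      min_record_years = min_record_years,
      min_samples_accumulated = min_samples_accumulated
    ),
    class = "analysis_window"
  )
}

#' Restrict a site to its fire-to-fire analysis period
#'
#' Truncates the record to `[first qualifying fire year, last fire year]`
#' within the window. The first qualifying fire is the earliest fire at or
#' after the year in which `min_samples_accumulated` series are simultaneously
#' alive (when that rule is on). Sites whose truncated span falls below
#' `min_record_years` are not rejected outright but flagged; see
#' [is_short_record()].
#'
#' @param site A [fhx_site()].
#' @param window An [analysis_window()].
#' @return The truncated `fhx_site`, carrying attributes `analysis_window`
#'   and `short_record`.
#' @export
restrict_analysis_period <- function(site, window = analysis_window()) {
  stopifnot(is_fhx_site(site), inherits(window, "analysis_window"))
  fires <- scar_years(site)
  fires_in <- fires[fires >= window$start_year & fires <= window$end_year]
  if (length(fires_in) == 0) {
    rlang::abort(
      sprintf(
        "no usable record: site '%s' has no fire years in %d-%d",
        fhx_meta(site)$site_id, window$start_year, window$end_year
      ),
      class = "firerate_error_no_usable_record"
    )
  }
  first_fire <- min(fires_in)
  if (window$min_samples_accumulated > 0) {
    depth <- site |>
      dplyr::summarise(n_alive = dplyr::n_distinct(.data$series),
                       .by = "year") |>
      dplyr::arrange(.data$year)
    deep <- depth$year[depth$n_alive >= window$min_samples_accumulated]
    if (length(deep) == 0) {
      rlang::abort(
        sprintf(
          "no usable record: sample depth never reaches %d series",
          window$min_samples_accumulated
        ),
        class = "firerate_error_no_usable_record"
      )
    }
    qualifying <- fires_in[fires_in >= min(deep)]
    if (length(qualifying) == 0) {
      rlang::abort(
        "no usable record: no fire at or after the sample-depth year",
        class = "firerate_error_no_usable_record"
      )
    }
    first_fire <- min(qualifying)
  }
  last_fire <- max(fires_in)
  out <- dplyr::filter(site, .data$year >= first_fire, .data$year <= last_fire)
  out <- new_fhx_site(tibble::as_tibble(out), fhx_meta(site))
  attr(out, "analysis_window") <- window
  attr(out, "short_record") <- (last_fire - first_fire) < window$min_record_years
  out
}

#' @rdname restrict_analysis_period
#' @export
is_short_record <- function(site) isTRUE(attr(site, "short_record"))
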