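#' Ratio-method area burned for a fire year
#'
#' The non-spatial ratio method allocates to fire year `i` an area
#' proportional to the fraction of scarred trees (or plots) recording it:
#' `A_i = AT * NS_i / (NST - NRE)`, where `AT` is the study-area size, `NS_i`
#' the number of scarred trees or plots recording year `i`, `NST` the total
#' number of scarred trees or plots, and `NRE` the number eliminated by
#' subsequent fires.
#'
#' @param at Study-area size (ha), `> 0`.
#' @param ns_i Scarred trees/plots recording year `i` (vectorized).
#' @param nst Total scarred trees/plots.
#' @param nre Scarred trees/plots eliminated by subsequent fires (default 0).
#' @return Area burned in year `i`, in hectares.
#' @export
ratio_area_burned <- function(at, ns_i, nst, nre = 0) {
  if (at <= 0) {
    rlang::abort("study area AT must be > 0", class = "firerate_error_ratio")
  }
  if (any(ns_i < 0) || any(ns_i > nst)) {
    rlang::abort("NS_i must lie in [0, NST]", class = "firerate_error_ratio")
  }
  if (nst - nre <= 0) {
    rlang::abort("NST - NRE must be > 0: ratio denominator undefined",
      class = "firerate_error_ratio"
    )
  }
  at * ns_i / (nst - nre)
}

#' Fire rotation
#'
#' `FR = observation_period / fraction_burned`: the expected time for
#' cumulative burned area to equal the landscape area. The burned fraction is
#' the sum of per-fire burned fractions over the observation period and may
#' exceed 1.
#'
#' @param observation_period Length of the record, in years (`> 0`).
#' @param fraction_burned Summed burned fraction (`> 0` for a finite FR).
#' @return Fire rotation in years.
#' @export
fire_rotation <- function(observation_period, fraction_burned) {
  if (observation_period <= 0) {
    rlang::abort("observation_period must be > 0",
      class = "firerate_error_rotation"
    )
  }
  if (fraction_burned <= 0) {
    rlang::abort("fraction_burned is 0: fire rotation is infinite",
      class = "firerate_error_infinite_rotation"
    )
  }
  observation_period / fraction_burned
}

#' Fire rotation from a fire-scar site by the ratio method
#'
#' Converts a site's scar record into annual burned fractions and applies the
#' rotation equation. For each fire year after the record-opening fire, the
#' burned fraction is the number of series scarred that year over the number
#' of eligible series alive that year; with `basis = "total_scarred"` eligible
#' series are all series scarred at least once during the analysis period,
#' with `basis = "recorders"` only series already scarred by that year (a
#' series is a recorder from its first scar onward). The observation period is
#' the span from first to last fire year, and the opening fire initiates the
#' record rather than contributing burned area, so a single series scarred
#' every 20 years yields FR = 20 exactly.
#'
#' Per-year denominators use series alive in that year by default, so early
#' sparse periods do not deflate fractions; `denominator = "fixed_total"`
#' instead divides every year by `NST - nre`.
#'
#' @param site A [fhx_site()].
#' @param basis `"total_scarred"` or `"recorders"`.
#' @param window Optional [analysis_window()] applied first.
#' @param denominator `"per_year_alive"` (default) or `"fixed_total"`.
#' @param nre Series to deduct under `denominator = "fixed_total"`.
#' @return Fire rotation in years, with attribute `"by_year"` holding the
#'   per-fire-year fraction table.
#' @export
fr_from_site <- function(site, basis = c("total_scarred", "recorders"),
                         window = NULL,
                         denominator = c("per_year_alive", "fixed_total"),
                         nre = 0) {
  basis <- match.arg(basis)
  denominator <- match.arg(denominator)
  if (!is.null(window)) {
    site <- restrict_analysis_period(site, window)
  }
  fires <- scar_years(site)
  if (length(fires) < 2) {
    rlang::abort("insufficient intervals: need at least two fire years",
      class = "firerate_error_insufficient_intervals"
    )
  }
  spans <- series_spans(site)
  scarred <- spans[spans$n_scars > 0, ]
  if (nrow(scarred) == 0) {
    rlang::abort("no scarred series", class = "firerate_error_no_usable_record")
  }
  counts <- site |>
    dplyr::filter(is_scar_code(.data$code)) |>
    dplyr::summarise(n_scarred = dplyr::n_distinct(.data$series),
                     .by = "year")
  burn_years <- fires[-1] # the opening fire initiates the record
  by_year <- tibble::tibble(year = burn_years) |>
    dplyr::left_join(counts, by = "year")
  nst <- nrow(scarred)
  by_year$denom <- vapply(by_year$year, function(y) {
    alive <- scarred$first_year <= y & scarred$last_year >= y
    eligible <- switch(basis,
      total_scarred = alive,
      recorders = alive & !is.na(scarred$first_scar) & scarred$first_scar <= y
    )
    if (denominator == "fixed_total") {
      as.integer(nst - nre)
    } else {
      sum(eligible)
    }
  }, integer(1))
  if (any(by_year$denom <= 0)) {
    rlang::abort("zero eligible series in a fire year",
      class = "firerate_error_no_usable_record"
    )
  }
  by_year$fraction <- by_year$n_scarred / by_year$denom
  period <- max(fires) - min(fires)
  fr <- fire_rotation(period, sum(by_year$fraction))
  attr(fr, "by_year") <- by_year
  fr
}
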