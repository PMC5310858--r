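# Construct a site from per-series specs: list(first =, last =, scars =).
# Recording starts at the first scar, as in field practice.
manual_site <- function(specs, site_id = "manual", area_ha = NA_real_) {
  rows <- purrr::imap(specs, function(sp, i) {
    span <- sp$first:sp$last
    code <- rep(".", length(span))
    scars <- if (is.null(sp$scars)) integer(0) else sp$scars
    if (length(scars) > 0) {
      code[span >= min(scars)] <- "|"
      code[match(scars, span)] <- "U"
    }
    tibble::tibble(series = sprintf("T%02d", i), year = span, code = code)
  })
  df <- dplyr::bind_rows(rows)
  fhx_site(df$series, df$year, df$code, site_id = site_id, area_ha = area_ha)
}

# A small clustered-plot regime emulating a fire-history collection.
plot_config <- function(years = 400, n_trees = 15, ...) {
  regime_config(years = years, n_trees = n_trees, placement = "clustered", ...)
}
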