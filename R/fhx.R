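#' Fire-history site objects
#'
#' A `fhx_site` is a tibble holding a multi-tree fire-scar chronology in long
#' form: one row per series-year inside each tree's record span, with a single
#' FHX matrix character per row. Site-level metadata (sample area, coordinates,
#' forest type) travels in the `"fhx_meta"` attribute and is read with
#' [fhx_meta()].
#'
#' Matrix characters follow common FHX2 practice: any uppercase letter is a
#' fire scar (the letter encodes the intra-ring season and is preserved but
#' ignored by all statistics), any lowercase letter is a non-scar injury,
#' `|` is a recording year, `.` a non-recording year, `[`/`]` pith and bark
#' dates, and `{`/`}` estimated inner and outer dates.
#'
#' @param series Character vector of series (tree) labels.
#' @param year Integer vector of calendar years (CE).
#' @param code Character vector of single FHX matrix characters.
#' @param site_id Site label.
#' @param area_ha Sampled area in hectares, or `NA`.
#' @param latitude,longitude Decimal degrees, or `NA`.
#' @param forest_type One of `"dry_pine"`, `"dry_mixed_conifer"`, `"unknown"`.
#' @param state_code Two-letter state/province code, or `NA`.
#'
#' @return A tibble of class `fhx_site` with columns `series`, `year`, `code`.
#' @examples
#' site <- fhx_site(
#'   series = rep("T1", 5), year = 1700:1704,
#'   code = c("{", ".", "U", "|", "}"),
#'   site_id = "toy"
#' )
#' scar_years(site)
#' @export
fhx_site <- function(series, year, code, site_id = "site", area_ha = NA_real_,
                     latitude = NA_real_, longitude = NA_real_,
                     forest_type = c("unknown", "dry_pine", "dry_mixed_conifer"),
                     state_code = NA_character_) {
  forest_type <- match.arg(forest_type)
  df <- tibble::tibble(
    series = as.character(series),
    year = as.integer(year),
    code = as.character(code)
  )
  meta <- list(
    site_id = site_id, area_ha = area_ha, latitude = latitude,
    longitude = longitude, forest_type = forest_type, state_code = state_code
  )
  new_fhx_site(df, meta)
}

new_fhx_site <- function(df, meta) {
  validate_fhx_df(df, meta)
  df <- dplyr::arrange(df, .data$series, .data$year)
  attr(df, "fhx_meta") <- meta
  class(df) <- c("fhx_site", class(tibble::tibble()))
  df
}

validate_fhx_df <- function(df, meta) {
  if (any(nchar(df$code) != 1L)) {
    rlang::abort("all FHX codes must be single characters",
      class = "firerate_error_bad_code"
    )
  }
  bad_span <- df |>
    dplyr::summarise(
      contiguous = all(diff(sort(.data$year)) == 1L) || dplyr::n() == 1L,
      .by = "series"
    ) |>
    dplyr::filter(!.data$contiguous)
  if (nrow(bad_span) > 0) {
    rlang::abort(
      paste0(
        "series must span contiguous years: ",
        paste(bad_span$series, collapse = ", ")
      ),
      class = "firerate_error_bad_span"
    )
  }
  if (!is.na(meta$area_ha) && meta$area_ha <= 0) {
    rlang::abort("area_ha must be > 0 when present",
      class = "firerate_error_bad_meta"
    )
  }
  invisible(df)
}

#' @export
print.fhx_site <- function(x, ...) {
  meta <- fhx_meta(x)
  spans <- series_spans(x)
  cat(sprintf(
    "<fhx_site '%s'> %d series, %d-%d (%d scar years)\n",
    meta$site_id, nrow(spans), min(x$year), max(x$year),
    dplyr::n_distinct(scar_years(x))
  ))
  NextMethod()
}

#' Site metadata
#'
#' @param site A [fhx_site()].
#' @return A named list with elements `site_id`, `area_ha`, `latitude`,
#'   `longitude`, `forest_type`, `state_code`.
#' @export
fhx_meta <- function(site) {
  meta <- attr(site, "fhx_meta")
  if (is.null(meta)) {
    meta <- list(
      site_id = "site", area_ha = NA_real_, latitude = NA_real_,
      longitude = NA_real_, forest_type = "unknown",
      state_code = NA_character_
    )
  }
  meta
}

#' @rdname fhx_meta
#' @export
is_fhx_site <- function(site) inherits(site, "fhx_site")

is_scar_code <- function(code) grepl("^[A-Z]$", code)

#' Per-series record spans and scar years
#'
#' `series_spans()` tabulates each tree's first and last recorded year, scar
#' count, and first scar year (recorder eligibility begins at the first scar).
#' `scar_years()` returns the sorted unique fire-scar years on any series.
#'
#' @param site A [fhx_site()].
#' @return `series_spans()`: a tibble with one row per series;
#'   `scar_years()`: an integer vector.
#' @export
series_spans <- function(site) {
  site |>
    dplyr::summarise(
      first_year = min(.data$year),
      last_year = max(.data$year),
      n_scars = sum(is_scar_code(.data$code)),
      first_scar = if (any(is_scar_code(.data$code))) {
        min(.data$year[is_scar_code(.data$code)])
      } else {
        NA_integer_
      },
      .by = "series"
    )
}

#' @rdname series_spans
#' @export
scar_years <- function(site) {
  sort(unique(site$year[is_scar_code(site$code)]))
}

fhx_code_rx <- "^[][{}A-Za-z.|?]+"

#' Read an FHX fire-scar chronology
#'
#' Parses FHX2-dialect documents as distributed by the International
#' Multiproxy Paleofire Database: optional leading comment lines, a
#' `FHX2 FORMAT` (or `FIRE2 FORMAT`) declaration, a header giving the first
#' year, number of series and series-name length, vertically written series
#' names, then one row per year with one code column per series. Comment lines
#' of the form `# key: value` written by [write_fhx()] are restored as site
#' metadata; other unknown in-matrix characters are preserved as opaque
#' injury codes.
#'
#' @param file Path to an FHX file, or a character scalar containing the
#'   document itself (detected by an embedded newline).
#' @param site_id Site label; defaults to a `site_id` comment in the file or
#'   the file name.
#' @return A [fhx_site()].
#' @export
read_fhx <- function(file, site_id = NULL) {
  if (length(file) == 1 && grepl("\n", file)) {
    lines <- strsplit(file, "\n", fixed = TRUE)[[1]]
    src <- "text"
  } else {
    lines <- readr::read_lines(file)
    src <- basename(file)
  }
  decl <- grep("^\\s*(FHX2|FIRE2) FORMAT\\s*$", lines)
  if (length(decl) == 0) {
    rlang::abort("no 'FHX2 FORMAT' or 'FIRE2 FORMAT' declaration line found",
      class = "firerate_error_parse"
    )
  }
  decl <- decl[1]
  meta <- parse_fhx_comments(lines[seq_len(decl - 1)])
  hdr <- strsplit(trimws(lines[decl + 1]), "\\s+")[[1]]
  hdr_num <- suppressWarnings(as.integer(hdr))
  if (length(hdr_num) != 3 || anyNA(hdr_num)) {
    rlang::abort(
      sprintf(
        "malformed FHX header on line %d: expected '<first year> <n series> <name length>', got '%s'",
        decl + 1, lines[decl + 1]
      ),
      class = "firerate_error_parse"
    )
  }
  first_year <- hdr_num[1]
  n_series <- hdr_num[2]
  name_len <- hdr_num[3]
  name_lines <- lines[decl + 1 + seq_len(name_len)]
  name_lines[is.na(name_lines)] <- ""
  name_pad <- formatC(name_lines, width = n_series, flag = "-")
  series_names <- vapply(seq_len(n_series), function(j) {
    trimws(paste(substr(name_pad, j, j), collapse = ""))
  }, character(1))
  if (any(series_names == "")) {
    series_names[series_names == ""] <-
      paste0("S", which(series_names == ""))
  }
  body <- lines[-seq_len(decl + 1 + name_len)]
  body <- body[trimws(body) != ""]
  if (length(body) == 0) {
    rlang::abort("FHX document has no data rows", class = "firerate_error_parse")
  }
  codes <- matrix(".", nrow = length(body), ncol = n_series)
  for (i in seq_along(body)) {
    year_i <- first_year + i - 1L
    run <- regmatches(body[i], regexpr(fhx_code_rx, body[i]))
    n_cols <- if (length(run) == 0) 0L else nchar(run)
    trailing <- trimws(substring(body[i], n_cols + 1))
    if (nzchar(trailing)) {
      # a trailing year label is allowed; the code run must still be n_series
      yr <- suppressWarnings(as.integer(trailing))
      if (!is.na(yr) && yr != year_i) {
        rlang::abort(
          sprintf(
            "row year label %d disagrees with expected year %d", yr, year_i
          ),
          class = "firerate_error_parse"
        )
      }
    }
    if (n_cols != n_series) {
      rlang::abort(
        sprintf(
          "matrix row for year %d has %d series columns but header declares %d",
          year_i, n_cols, n_series
        ),
        class = "firerate_error_parse"
      )
    }
    codes[i, ] <- strsplit(substr(body[i], 1, n_series), "")[[1]]
  }
  years <- first_year + seq_along(body) - 1L
  long <- tibble::tibble(
    series = rep(series_names, each = length(years)),
    year = rep(years, times = n_series),
    code = as.vector(codes)
  )
  # record span: between the outermost non-'.' codes; all-'.' series span the
  # whole matrix (their status is simply never-recording)
  long <- long |>
    dplyr::mutate(
      .in_span = span_mask(.data$code),
      .by = "series"
    ) |>
    dplyr::filter(.data$.in_span) |>
    dplyr::select(-".in_span")
  if (!is.null(site_id)) meta$site_id <- site_id
  if (is.null(meta$site_id)) meta$site_id <- sub("\\.fhx$", "", src)
  meta <- utils::modifyList(default_meta(), meta)
  new_fhx_site(long, meta)
}

span_mask <- function(code) {
  idx <- which(code != ".")
  if (length(idx) == 0) {
    return(rep(TRUE, length(code)))
  }
  seq_along(code) >= min(idx) & seq_along(code) <= max(idx)
}

default_meta <- function() {
  list(
    site_id = NULL, area_ha = NA_real_, latitude = NA_real_,
    longitude = NA_real_, forest_type = "unknown", state_code = NA_character_
  )
}

parse_fhx_comments <- function(lines) {
  meta <- list()
  kv <- regmatches(lines, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.*)$", lines))
  for (m in kv) {
    if (length(m) == 3) {
      key <- m[2]
      val <- trimws(m[3])
      meta[[key]] <- switch(key,
        area_ha = , latitude = , longitude = as.numeric(val),
        val
      )
    }
  }
  meta
}

#' Write an FHX fire-scar chronology
#'
#' Emits a document that [read_fhx()] parses back to an identical site,
#' including site metadata (written as `# key: value` comment lines before the
#' format declaration, which other FHX readers ignore).
#'
#' @param site A [fhx_site()].
#' @param path Optional output path; when `NULL` the document is returned as a
#'   single string.
#' @return Invisibly (or visibly when `path` is `NULL`), the document text.
#' @export
write_fhx <- function(site, path = NULL) {
  stopifnot(is_fhx_site(site))
  spans <- series_spans(site)
  if (nrow(spans) == 0) {
    rlang::abort("site has no series", class = "firerate_error_empty")
  }
  meta <- fhx_meta(site)
  series_names <- unique(site$series)
  first_year <- min(site$year)
  last_year <- max(site$year)
  years <- first_year:last_year
  name_len <- max(nchar(series_names))
  codes <- matrix(".", nrow = length(years), ncol = length(series_names),
    dimnames = list(years, series_names)
  )
  codes[cbind(
    match(site$year, years),
    match(site$series, series_names)
  )] <- site$code
  name_block <- vapply(seq_len(name_len), function(k) {
    paste(substr(formatC(series_names, width = name_len, flag = "-"), k, k),
      collapse = ""
    )
  }, character(1))
  comment <- character(0)
  for (key in c("site_id", "area_ha", "latitude", "longitude", "forest_type",
                "state_code")) {
    val <- meta[[key]]
    if (!is.null(val) && !is.na(val)) {
      comment <- c(comment, sprintf("# %s: %s", key, format(val)))
    }
  }
  out <- c(
    comment,
    "FHX2 FORMAT",
    sprintf("%d %d %d", first_year, length(series_names), name_len),
    name_block,
    "",
    paste0(apply(codes, 1, paste, collapse = ""), " ", years)
  )
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    readr::write_lines(out, path)
    return(invisible(text))
  }
  text
}

#' Canonical estimator column names
#'
#' The 20 CFI/ITFI estimator columns (four families crossed with five measures
#' of central tendency) plus `fr_recorders`, the recorder-based fire-rotation
#' estimate, giving the 21 per-site rate estimators used throughout the
#' calibration workflow.
#'
#' @return A character vector of length 21.
#' @export
estimator_names <- function() {
  families <- c("cfi_all", "cfi10", "cfi25", "itfi")
  measures <- c("mean", "median", "weibull_scale", "weibull_mean",
                "weibull_median")
  c(as.vector(t(outer(measures, families, paste, sep = "_"))), "fr_recorders")
}

#' Read a per-site estimator table
#'
#' Ingests delimited-text exports of per-site calibration or prediction
#' datasets: one row per case, columns for interval/rate estimators,
#' the PMFI/FR reference values, sample-size covariates, and grouping fields.
#' Cells such as `"n/a"` become missing values and the row is retained; cells
#' that fail numeric parsing in a declared numeric column are reported by row,
#' never silently dropped.
#'
#' @param file Path to a delimited text file (or literal text with newlines).
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(weibull_mean_itfi = "WMean ITFI")`.
#' @param required Character vector of canonical columns that must be present
#'   after renaming; a missing one is an error naming it.
#' @param delim Field delimiter (default `","`).
#' @return A tibble with canonical column names where mapped.
#' @export
read_site_table <- function(file, schema = NULL, required = character(),
                            delim = ",") {
  if (length(file) == 1 && grepl("\n", file)) {
    file <- I(file)
  }
  tab <- readr::read_delim(file,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    na = c("", "NA", "n/a", "N/A", "na", "-")
  )
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(tab))
    if (length(missing_src) > 0) {
      rlang::abort(
        paste0("schema refers to absent columns: ",
               paste(missing_src, collapse = ", ")),
        class = "firerate_error_schema"
      )
    }
    names(tab)[match(unname(schema), names(tab))] <- names(schema)
  }
  missing_req <- setdiff(required, names(tab))
  if (length(missing_req) > 0) {
    rlang::abort(
      paste0("mandatory column(s) missing: ",
             paste(missing_req, collapse = ", ")),
      class = "firerate_error_schema"
    )
  }
  numeric_cols <- intersect(
    c(estimator_names(), "pmfi_fr_total", "pmfi_fr", "sample_area_ha",
      "total_scarred_trees", "scarred_trees_per_100ha", "beginning_year"),
    names(tab)
  )
  for (col in numeric_cols) {
    if (!is.numeric(tab[[col]])) {
      raw <- tab[[col]]
      parsed <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(parsed) & !is.na(raw))
      if (length(bad) > 0) {
        rlang::warn(sprintf(
          "column '%s': %d cell(s) failed numeric parsing (rows %s); kept as missing",
          col, length(bad), paste(utils::head(bad, 5), collapse = ", ")
        ))
      }
      tab[[col]] <- parsed
    }
  }
  tab
}
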