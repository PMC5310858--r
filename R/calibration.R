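#' Bias and inaccuracy of rate estimators
#'
#' For each estimator column, computes relative mean error
#' `RME = mean((M_i - FR_i) / FR_i)` and relative mean absolute error
#' `RMAE = mean(|M_i - FR_i| / FR_i)` against the reference PMFI/FR column,
#' both expressed in percent, over the estimator's own complete-case pairs.
#' One-sample two-sided t-tests of mean zero quantify whether bias and
#' inaccuracy are significant; with fewer than two pairs only the values are
#' reported.
#'
#' @param data A data frame of per-site estimator values (one row per case).
#' @param estimators <[`tidy-select`][dplyr::dplyr_tidy_select]> Estimator
#'   columns to evaluate.
#' @param reference Name of the reference PMFI/FR column (default
#'   `"pmfi_fr_total"`).
#' @return A tibble with one row per estimator: `estimator`, `n`, `mean_rme`,
#'   `se_rme`, `t_bias`, `p_bias`, `mean_rmae`, `se_rmae`, `t_inacc`,
#'   `p_inacc` (percent scales).
#' @export
bias_inaccuracy <- function(data, estimators, reference = "pmfi_fr_total") {
  est_cols <- names(dplyr::select(tibble::as_tibble(data), {{ estimators }}))
  if (!reference %in% names(data)) {
    rlang::abort(sprintf("reference column '%s' not found", reference),
      class = "firerate_error_schema"
    )
  }
  fr <- data[[reference]]
  purrr::map_dfr(est_cols, function(col) {
    m <- data[[col]]
    ok <- !is.na(m) & !is.na(fr) & fr > 0
    rel <- 100 * (m[ok] - fr[ok]) / fr[ok]
    arel <- abs(rel)
    n <- sum(ok)
    row <- tibble::tibble(
      estimator = col, n = n,
      mean_rme = mean(rel), se_rme = stats::sd(rel) / sqrt(n),
      t_bias = NA_real_, p_bias = NA_real_,
      mean_rmae = mean(arel), se_rmae = stats::sd(arel) / sqrt(n),
      t_inacc = NA_real_, p_inacc = NA_real_
    )
    if (n >= 2 && stats::sd(rel) > 0) {
      tb <- stats::t.test(rel, mu = 0)
      ti <- stats::t.test(arel, mu = 0)
      row$t_bias <- unname(tb$statistic)
      row$p_bias <- tb$p.value
      row$t_inacc <- unname(ti$statistic)
      row$p_inacc <- ti$p.value
    }
    row
  })
}

#' Through-origin calibration regression
#'
#' Fits the no-intercept least-squares model `reference = slope * predictor`
#' used to convert CFI/ITFI estimator values into PMFI/FR, iteratively
#' removing up to `max_outliers` cases whose externally studentized residual
#' exceeds `outlier_threshold` (largest first, refitting after each removal).
#' The adjusted R-squared is the uncentered definition standard for
#' through-origin models.
#'
#' @param data A data frame with the predictor and response columns.
#' @param predictor Name of the estimator column.
#' @param response Name of the reference PMFI/FR column.
#' @param outlier_threshold Externally studentized residual cutoff
#'   (default 3).
#' @param max_outliers Maximum cases removed (default 2).
#' @param case_id Optional name of a case-identifier column used to report
#'   removed outliers; row numbers are used otherwise.
#' @param min_cases Minimum complete pairs required (default 10).
#' @return An object of class `fire_calibration` with elements `predictor`,
#'   `response`, `slope`, `coefs`, `covariates`, `n`, `removed_outliers`,
#'   `r2_adj`, `fit` (the `lm`), and `data` (post-removal cases).
#' @export
fit_origin_regression <- function(data, predictor,
                                  response = "pmfi_fr_total",
                                  outlier_threshold = 3, max_outliers = 2,
                                  case_id = NULL, min_cases = 10) {
  df <- calibration_frame(data, predictor, response, character(), case_id)
  if (nrow(df) < min_cases) {
    rlang::abort(
      sprintf("need at least %d complete pairs, have %d", min_cases, nrow(df)),
      class = "firerate_error_too_few_cases"
    )
  }
  if (all(df$x == 0)) {
    rlang::abort("all predictor values are zero",
      class = "firerate_error_degenerate"
    )
  }
  res <- prune_outliers(df, y ~ 0 + x, outlier_threshold, max_outliers)
  new_fire_calibration(
    res, predictor, response,
    covariates = character(),
    term_names = c(predictor)
  )
}

calibration_frame <- function(data, predictor, response, covariates, case_id) {
  need <- c(predictor, response, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")),
      class = "firerate_error_schema"
    )
  }
  ids <- if (!is.null(case_id) && case_id %in% names(data)) {
    data[[case_id]]
  } else {
    seq_len(nrow(data))
  }
  df <- tibble::tibble(
    case = ids,
    x = data[[predictor]],
    y = data[[response]]
  )
  for (cv in covariates) df[[cv]] <- data[[cv]]
  df[stats::complete.cases(df), ]
}

prune_outliers <- function(df, formula, outlier_threshold, max_outliers) {
  removed <- df$case[0]
  scale <- sqrt(mean(df$y^2))
  repeat {
    fit <- stats::lm(formula, data = df)
    if (length(removed) >= max_outliers) break
    res <- stats::residuals(fit)
    if (max(abs(res)) <= 1e-8 * scale) break # numerically exact fit
    rs <- stats::rstudent(fit)
    # a non-finite externally studentized residual arises when the remaining
    # points fit exactly: that point is an unbounded outlier
    bad <- !is.finite(rs)
    rs[bad] <- ifelse(abs(res[bad]) > 1e-8 * scale, Inf, 0)
    worst <- which.max(abs(rs))
    if (length(worst) == 0 || abs(rs[worst]) <= outlier_threshold) {
      break
    }
    removed <- c(removed, df$case[worst])
    df <- df[-worst, ]
  }
  list(fit = fit, data = df, removed = removed)
}

new_fire_calibration <- function(res, predictor, response, covariates,
                                 term_names) {
  fit <- res$fit
  coefs <- stats::coef(fit)
  names(coefs) <- term_names
  structure(
    list(
      predictor = predictor, response = response,
      slope = unname(coefs[1]), coefs = coefs, covariates = covariates,
      n = nrow(res$data), removed_outliers = res$removed,
      r2_adj = summary(fit)$adj.r.squared,
      fit = fit, data = res$data
    ),
    class = "fire_calibration"
  )
}

#' @export
print.fire_calibration <- function(x, ...) {
  cat(sprintf(
    "<fire_calibration> %s = %.4g * %s%s\n  n = %d (%s outlier%s removed), R2_adj = %.4f\n",
    x$response, x$slope, x$predictor,
    if (length(x$covariates) > 0) {
      paste0(" + ", paste(sprintf("%.4g*%s", x$coefs[-1], x$covariates),
        collapse = " + "
      ))
    } else {
      ""
    },
    x$n, length(x$removed_outliers),
    if (length(x$removed_outliers) == 1) "" else "s",
    x$r2_adj
  ))
  invisible(x)
}

#' Cross-validated prediction error of a calibration model
#'
#' K-fold cross-validation of a fitted [fit_origin_regression()] (or
#' best-subset) model on its post-outlier-removal cases: cases are assigned to
#' folds by a seeded shuffle, the model is refitted on each training portion,
#' and the root mean square prediction error on held-out cases is returned.
#' Cases are canonically ordered before shuffling, so the result depends only
#' on the data content and seed, not on row order.
#'
#' @param model A `fire_calibration` object.
#' @param folds Number of folds (default 10); reduced with a warning when the
#'   sample is smaller.
#' @param seed Integer seed for the fold assignment.
#' @return The cross-validated RMSE in years.
#' @export
cross_validate <- function(model, folds = 10, seed = 1) {
  stopifnot(inherits(model, "fire_calibration"))
  df <- model$data
  n <- nrow(df)
  if (n < folds) {
    rlang::warn(sprintf("reducing folds from %d to n = %d", folds, n))
    folds <- n
  }
  df <- df[order(df$case, df$x, df$y), ]
  perm <- withr::with_seed(seed, sample.int(n))
  fold_of <- rep_len(seq_len(folds), n)[order(perm)]
  sq_err <- numeric(n)
  fml <- stats::formula(model$fit)
  for (k in seq_len(folds)) {
    test <- fold_of == k
    fit_k <- stats::lm(fml, data = df[!test, ])
    pred <- stats::predict(fit_k, newdata = df[test, ])
    sq_err[test] <- (df$y[test] - pred)^2
  }
  sqrt(mean(sq_err))
}

#' Best-subset calibration with sample-size covariates
#'
#' Re-fits the through-origin calibration allowing sample-size covariates
#' (sample area, total scarred trees, scarred trees per 100 ha) alongside the
#' estimator. All subsets containing the estimator are enumerated; Mallow's
#' Cp is computed against the full model; among subsets whose every term is
#' significant at `alpha`, the lowest-Cp subset wins. When no covariate
#' qualifies the estimator-only model is returned. Outlier removal (as in
#' [fit_origin_regression()]) is applied to the full model's case set before
#' selection.
#'
#' @inheritParams fit_origin_regression
#' @param covariates Candidate sample-size covariate columns.
#' @param alpha Per-coefficient significance level for admission
#'   (default 0.05).
#' @return A `fire_calibration` whose `coefs` holds the estimator slope and
#'   any selected covariate coefficients.
#' @export
best_subsets_with_sample_size <- function(data, predictor,
                                          covariates = c(
                                            "sample_area_ha",
                                            "total_scarred_trees",
                                            "scarred_trees_per_100ha"
                                          ),
                                          response = "pmfi_fr_total",
                                          alpha = 0.05,
                                          outlier_threshold = 3,
                                          max_outliers = 2,
                                          case_id = NULL, min_cases = 10) {
  df <- calibration_frame(data, predictor, response, covariates, case_id)
  if (nrow(df) < min_cases) {
    rlang::abort(
      sprintf("need at least %d complete cases, have %d", min_cases, nrow(df)),
      class = "firerate_error_too_few_cases"
    )
  }
  full_terms <- c("x", covariates)
  full_formula <- stats::reformulate(c("0", full_terms), response = "y")
  pruned <- prune_outliers(df, full_formula, outlier_threshold, max_outliers)
  df <- pruned$data
  n <- nrow(df)
  full_fit <- stats::lm(full_formula, data = df)
  mse_full <- sum(stats::residuals(full_fit)^2) /
    stats::df.residual(full_fit)
  subsets <- purrr::map(
    seq(0, length(covariates)),
    ~ utils::combn(covariates, .x, simplify = FALSE)
  ) |> purrr::flatten()
  candidates <- purrr::map_dfr(subsets, function(cv) {
    terms <- c("x", cv)
    fit <- stats::lm(stats::reformulate(c("0", terms), response = "y"),
      data = df
    )
    p <- length(terms)
    sse <- sum(stats::residuals(fit)^2)
    cp <- sse / mse_full - (n - 2 * p)
    pvals <- summary(fit)$coefficients[, "Pr(>|t|)"]
    tibble::tibble(
      covs = list(cv), cp = cp,
      all_significant = all(pvals < alpha)
    )
  })
  admissible <- candidates[candidates$all_significant, ]
  chosen <- if (nrow(admissible) == 0) {
    character(0)
  } else {
    admissible$covs[[which.min(admissible$cp)]]
  }
  terms <- c("x", chosen)
  fit <- stats::lm(stats::reformulate(c("0", terms), response = "y"),
    data = df
  )
  new_fire_calibration(
    list(fit = fit, data = df, removed = pruned$removed),
    predictor, response,
    covariates = chosen,
    term_names = c(predictor, chosen)
  )
}

#' Predict PMFI/FR from an estimator value
#'
#' Applies a fitted calibration model to new estimator values: `slope * value`
#' for slope-only models, or the full linear combination when the model
#' carries sample-size covariates (pass a data frame in that case).
#'
#' @param value A positive numeric vector of estimator values, or a data
#'   frame holding the predictor and any covariate columns.
#' @param model A `fire_calibration`.
#' @return Predicted PMFI/FR in years (`NA` where the predictor is missing).
#' @export
predict_pmfi_fr <- function(value, model) {
  stopifnot(inherits(model, "fire_calibration"))
  if (is.data.frame(value)) {
    newdata <- tibble::tibble(x = value[[model$predictor]])
    for (cv in model$covariates) newdata[[cv]] <- value[[cv]]
    return(unname(stats::predict(model$fit, newdata = newdata)))
  }
  if (length(model$covariates) > 0) {
    rlang::abort(
      "model has covariates: supply a data frame with the covariate columns",
      class = "firerate_error_bad_input"
    )
  }
  if (any(value <= 0, na.rm = TRUE)) {
    rlang::abort("estimator values must be > 0",
      class = "firerate_error_bad_input"
    )
  }
  model$slope * value
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration model
#'
#' @param x A `fire_calibration`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.fire_calibration <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = names(x$coefs),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' Glance at a calibration model
#'
#' @param x A `fire_calibration`.
#' @param ... Unused.
#' @return A one-row tibble: `predictor`, `slope`, `n`, `r2_adj`,
#'   `n_outliers_removed`, `sigma`.
#' @export
glance.fire_calibration <- function(x, ...) {
  tibble::tibble(
    predictor = x$predictor, slope = x$slope, n = x$n, r2_adj = x$r2_adj,
    n_outliers_removed = length(x$removed_outliers),
    sigma = summary(x$fit)$sigma
  )
}
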