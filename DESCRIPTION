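Package: firerate
Title: Calibrated Estimation of Historical Low-Severity Fire Rates from
    Tree-Ring Fire-Scar Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing historical rates of low-severity fire in
    dry conifer forests from multi-tree fire-scar chronologies. Reads and
    writes FHX-format (Fire History Exchange) files, builds composite fire
    chronologies under the standard analysis-period restrictions, computes the
    composite fire interval (CFI) and individual-tree fire interval (ITFI)
    estimator families (mean, median, and two-parameter Weibull summaries),
    estimates fire rotation by the scarred-tree ratio method, quantifies
    estimator bias and inaccuracy against population mean fire interval / fire
    rotation (PMFI/FR), fits through-origin calibration regressions with
    studentized-residual outlier screening, cross-validated prediction error
    and best-subset sample-size models, and summarizes predicted historical
    rates across site collections. A stochastic landscape fire-regime
    simulator with known true PMFI and FR, imperfect scarring, and targeted
    sampling supports validation of the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
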