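---
title: "Calibrating fire-interval statistics to population fire rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating fire-interval statistics to population fire rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firerate)
library(dplyr)
```

## The problem

Tree-ring fire-scar chronologies are the main evidence for how often
low-severity fires burned the dry pine and dry mixed-conifer forests of the
western USA before EuroAmerican settlement. The statistics traditionally
computed from those chronologies, however, were designed to date fire years,
not to measure rates of burning. The two most common ones are:

* the **composite fire interval (CFI)** family: pool the fire-scar years of
  all sampled trees into one composite list and average the gaps between
  successive years, optionally keeping only "larger" fires that scarred at
  least 10% or 25% of the scarred samples alive in that year;
* the **individual-tree fire interval (ITFI)** family: average the intervals
  on each tree separately, then take the grand mean (or median) across trees.

Neither estimates the quantity a fire manager needs, the landscape's
**population mean fire interval (PMFI)** — the grand mean interval between
fires across all points of the landscape — or its equivalent, the **fire
rotation (FR)**, the expected time for cumulative burned area to equal the
landscape area. Compositing across many trees shortens intervals (any tree's
scar adds a fire year), so CFI measures run far below PMFI/FR; individual
trees miss fires because the **scarring fraction (SF)** — the share of live
trees inside a fire perimeter that actually receive a scar — is well below
one, so ITFI measures run long at a point but are also distorted by targeted
sampling of multi-scarred trees.

This package implements the calibration route between the two worlds: compute
the estimator families exactly as practitioners do, quantify their bias and
inaccuracy against PMFI/FR, fit through-origin regressions that convert an
estimator value into a PMFI/FR estimate, and summarize calibrated rates
across site collections. Every stage is validated against a stochastic
landscape fire-regime simulator in which the true PMFI and FR are known.

## Data model and restriction rules

Chronologies are held as `fhx_site` tibbles (one row per series-year, one FHX
matrix character per row) read and written by `read_fhx()`/`write_fhx()` in
the FHX2 exchange dialect. Any uppercase letter is a fire scar (the letter is
a season code, preserved but ignored — all statistics here are annual),
lowercase letters are non-scar injuries, `|`/`.` are recording and
non-recording years, and `[]{}` are pith/bark/inner/outer boundary markers.

Interval statistics are computed scar-to-scar. `restrict_analysis_period()`
truncates a site to the span from the earliest to the latest fire inside a
calendar window (1600–1900 CE by default), optionally starting only at the
first fire after a minimum sample depth (10 series alive, by default) has
accumulated; sample depth counts series alive between their boundary dates,
not series already scarred. Restricted spans shorter than 50 years are
flagged rather than silently dropped (`is_short_record()`).

Two conventions in `composite_fire_years()` are genuinely underdetermined in
field practice and are therefore explicit options:

* **threshold rule** — whether a fire on *exactly* 10%/25% of scarred samples
  qualifies. The default is `>=` (it does), with `"gt"` available; a fixture
  in the test suite documents both.
* **denominator** — percent scarred is computed against series that are alive
  in that year *and* scarred at least once during the analysis period
  ("scarred samples"), not against all series or recorders only.

## Fire rotation by the ratio method

`ratio_area_burned()` implements the classic ratio estimator: the area
attributed to fire year *i* is the study area times the share of scarred
trees (or plots) recording that year, `A_i = AT * NS_i / (NST - NRE)`.
`fire_rotation()` divides the observation period by the summed burned
fraction. `fr_from_site()` applies both to a scar record directly, on either
a total-scarred-trees or a recorders basis (a tree is a recorder from its
first scar onward).

One convention had to be fixed here: with a fire-to-fire restricted record,
the observation period is taken as last-minus-first fire year and the
record-opening fire is treated as initiating the record rather than
contributing burned area. Under this convention a single series scarred every
20 years yields FR = 20 exactly, consistent with the point-interval view, and
the estimator converges to the simulator's true rotation under dense,
perfectly scarring sampling (relative error about 3% at 50 trees over 500
years in the validation runs). Per-year denominators use series alive in that
year, so sparse early decades do not deflate fractions; a `fixed_total`
denominator with an explicit `nre` deduction is available for comparison with
published ratio estimates.

## Bias, inaccuracy and calibration

`bias_inaccuracy()` scores any estimator column against a reference PMFI/FR
column by relative mean error (signed bias) and relative mean absolute error,

$$\mathrm{RME} = \frac{1}{n}\sum_i \frac{M_i - FR_i}{FR_i}, \qquad
  \mathrm{RMAE} = \frac{1}{n}\sum_i \frac{|M_i - FR_i|}{FR_i},$$

in percent, with one-sample two-sided t-tests of zero mean. Each estimator
uses its own complete-case pairs, since estimator availability varies across
real compilations.

`fit_origin_regression()` fits the conversion model
`PMFI/FR = slope * estimator` by no-intercept least squares. Outlier handling
follows the screening rule used in published calibrations of this kind:
iteratively remove up to two cases whose *externally* studentized residual
exceeds 3.0, largest first, refitting after each removal. Two numerical
details are worth stating. First, for a through-origin model the reported
adjusted R-squared is the uncentered definition (the standard output for
no-intercept least squares). Second, when the remaining points fit exactly,
the externally studentized residual of a gross outlier is infinite and
`rstudent()` returns `NaN`; the pruner treats such points as unbounded
outliers, and stops outright when residuals are numerically zero so that
floating-point noise can never masquerade as an outlier.

`cross_validate()` reports 10-fold cross-validated RMSE on the
post-screening cases. Fold assignment is a seeded shuffle of canonically
ordered cases, so the result depends only on data content and seed — but it
*does* depend on the seed, so cross-validated RMSEs carry fold-assignment
noise of a few tenths of a year and should be compared as bands, not digits.

`best_subsets_with_sample_size()` re-fits the calibration allowing
sample-size covariates (sample area, total scarred trees, scarred trees per
100 ha), enumerating all subsets that contain the estimator, computing
Mallow's Cp against the full model, and keeping the lowest-Cp subset whose
every term is significant at 0.05. With per-term admission at 5%, occasional
chance admissions under the null are expected — the test suite checks the
selection behavior across replicates, not on single draws. Note that in a
no-intercept model a strictly positive covariate can act as a quasi-
intercept; this is inherent to the published model form, not an artifact of
this implementation.

`summarize_rates()` produces the descriptive block used for site
collections (n, mean with t-interval, sd, CV, quartiles, median with
interval, extremes). The median interval is a distribution-free
order-statistic (binomial) interval, linearly interpolated toward nominal
95% coverage; spreadsheet statistics packages use different interpolation
schemes, so median intervals from other software are matched only
approximately. CV uses the sample (n−1) standard deviation; single-member
groups report spread statistics as missing. `rate_histogram()` uses
half-open bins anchored at zero and reports strict exceedance percentages at
bin lower limits, because exceedance shares ("x% of sites have PMFI/FR above
25 years") are robust to bin anchoring while bin counts are not.
`old_forest_proxy()` encodes the beginning-year age proxy (before 1700 →
at least 200 years old by 1900; before 1750 → at least 150),
`low_severity_classifier()` the three-threshold structural model
(< 178 trees/ha, > 29.2% large trees, < 46.9% small trees, all strict), and
`area_weighted_percentage()` pools landscape areas by hectares.

## The simulator

`simulate_regime()` generates the ground truth that none of the field data
can provide. The landscape is a grid of 1-ha cells (20 × 20 by default).
Each year a Poisson number of fires ignites (0.65/yr by default); each fire
burns a contiguous, roughly square patch whose landscape fraction is drawn
from a truncated power law (exponent 1.8 on [0.005, 1]), placed uniformly
*with toroidal wraparound* so that every cell has the same long-run burn
rate. Homogeneity is what makes the regime's PMFI and FR provably equal, and
the simulated truth reproduces that equivalence to well under 5% over 2000
years — the package's core self-check. The defaults imply a landscape mean
fire interval near 40 years (0.65 fires/yr × ~3.8% mean burned fraction),
in the multidecadal range typical of western dry forests.

Sampled trees scar imperfectly: a tree inside a fire perimeter receives a
scar with probability 0.3 before its first scar and 0.7 afterwards,
reflecting the elevated susceptibility of recorder trees. These scarring
fractions are working conventions chosen for testing, not field estimates —
no quantitative SF measurements were available to anchor them. Trees live
the whole span by default; `staggered_ages = TRUE` staggers establishment
years to exercise the sample-depth logic. Patch geometry is deliberately
simple (axis-aligned blocks): the statistics under study depend on burned
fraction and on which trees co-burn, not on perimeter shape.

Tree placement matters more than any other knob. A real fire-scar collection
is a compact plot inside a much larger fire-shed, and the compositing bias
exists precisely because fires larger than the plot scar many of its trees
at once. The bias and calibration experiments therefore use
`placement = "clustered"` (the sampled trees occupy a compact block of
cells) as their study condition; with trees scattered uniformly over the
whole landscape the 25%-scarred filter instead starves (no single fire
covers a quarter of such a sample) and its bias flips long — a regime no
real plot collection occupies. Under the clustered condition the simulated
bias table reproduces the structure seen in real calibrations: mean CFI-all
around −65%, shrinking monotonically through the 10% and 25% filters, with
tree-level (ITFI) measures biased long because SF < 1.

`targeted_subsample()` emulates the near-universal field practice of seeking
multi-scarred trees, and `bias_experiment()` / `calibration_experiment()`
assemble many simulated sites into bias tables and calibration datasets,
with per-site ignition rates drawn log-uniformly over a configurable range
so that calibration fits see the broad rate spread (roughly 10–300 years)
present in real compilations.

What the simulator does *not* emulate: climate forcing and temporal
autocorrelation of fire years; fire severity (all simulated fires are
understory burns); tree mortality from fire; spatial gradients in fire rate;
dating error. Passing validation therefore demonstrates that the estimators
and the calibration machinery behave correctly under a known homogeneous
regime with imperfect observation — it does not demonstrate that any real
landscape satisfies those assumptions.

## Numerical choices

* **Weibull fits** (`fit_weibull()`): two-parameter maximum likelihood with
  the shift fixed at zero, since published per-site Weibull summaries report
  scale/mean/median without a shift and MLE is reproducible. Fewer than
  three intervals, zero-variance interval sets and non-convergence all
  return a missing fit, mirroring the variable estimator availability of
  real compilations. Which fitting routine produced any given published
  Weibull value is generally unstated, so percent-level differences from
  other software are expected.
* **Weibull ITFI measures** are fitted to the pooled individual-tree
  intervals (every inter-scar interval on every tree), while mean/median
  ITFI are the unweighted grand mean/median of per-tree means. Pooling
  weights multi-scarred (short-interval) trees more heavily, which is why
  Weibull mean ITFI runs shorter than mean ITFI — the same ordering seen in
  real calibration tables.
* **Interval resolution** is integer years; two scars in one year on
  different trees are one composite fire year.
* **Calibration recovery with collection size**: out-of-sample prediction
  RMSE against truth is flat across feasible collection sizes because the
  single slope converges quickly and irreducible per-site variability
  dominates. The component that does shrink with collection size is the
  slope's standard error, and that (plus the closure property that
  calibrated predictions beat the uncorrected estimator whenever simulated
  bias is nonzero) is what the test suite asserts.

## Validation problem sizes

The shipped validation uses: 2000-year runs for the PMFI/FR equivalence
check; 5000 intervals for Weibull parameter recovery (within 5%); 20
simulated plots of 400 years and 20 trees for the bias table; 50 trees over
500 years for ratio-method convergence; 96- and 60-site synthetic
calibration collections for the regression workflow; 100 simulated sites for
FHX round-trip identity; and 24 replicates for the targeting experiment.
These sizes were chosen so the full suite demonstrates each property with
comfortable margins while remaining quick to run end-to-end.

## Limitations

The original multi-study calibration and merged prediction datasets are
published supplementary spreadsheets and are not redistributed here; the
workflows that consume them (`read_site_table()` with a schema map, then
`bias_inaccuracy()`, `fit_origin_regression()`, `summarize_rates()`) are
exercised end-to-end on simulator output instead, and the package's
acceptance checks state explicitly which published values require the
original exports. Season codes are parsed but unused; no fire-year mapping
(Voronoi, kriging, hulls) is attempted; and no climate or seasonality
analysis is in scope.
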