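Package: heatfe
Title: Temperature and County-Level Death Rates via High-Dimensional
    Fixed-Effects Panel Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking monthly ambient temperature to county-level
    outcome rates with two-way high-dimensional fixed-effects weighted panel
    regression. Implements within-transformation (alternating-projection)
    estimation with county-month and state-year fixed effects, population
    weights and county-clustered robust covariance; natural-cubic-spline,
    polynomial and B-spline exposure-response bases with AIC model selection
    and baseline-anchored response curves; distributed-lag (displacement)
    effects; interaction, binned and categorical heterogeneity analyses;
    inverse-distance-weighted interpolation of station meteorology to county
    centroids; and projection of cumulative excess deaths under future
    warming with bootstrap-by-climate-model Monte Carlo uncertainty. A
    synthetic county-month panel generator with fully known ground truth
    supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
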