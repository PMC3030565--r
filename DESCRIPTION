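Package: divezoc
Title: Zero-Offset Correction of Dive Depth from Time-Depth Recorders by
    Recursive Moving-Quantile Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects baseline (zero-offset) error in diving-depth time
    series recorded by time-depth recorders (TDRs). Pressure transducers
    drift and shift over a deployment, so readings taken at the sea
    surface deviate from zero; the package estimates the wandering
    surface level by recursively applying center-aligned running
    quantiles with user-chosen window widths and quantile fractions,
    optionally restricted to a depth band where the surface is expected,
    and subtracts that estimate from the record. Includes a synthetic
    dive-record simulator with noise, drift, level-shift and missing-gap
    corruption operators for parameter-recovery experiments, RMSE and
    Kolmogorov-Smirnov evaluation of corrections against a known clean
    record, tidy/glance/augment methods, ggplot2 plots, and a
    command-line interface with shipped filter recipes for several
    diving-species regimes.
License: GPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
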