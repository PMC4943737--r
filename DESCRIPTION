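Package: baltind
Title: Zooplankton Community Indicators and Control-Chart Assessment of
    Environmental Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes nine summer zooplankton community indicators (total
    stock as abundance and biomass, copepod and microphagous biomass and
    their contributions to the total, mean individual size, and
    cladoceran/rotifer to calanoid copepod biomass ratios) from
    taxon-resolved monitoring samples, and assesses environmental status
    against reference conditions with statistical process control.
    Indicator series are Box-Cox transformed, gap-imputed by iterative
    eigenvector filtering, and standardized to z-scores against
    configurable baselines (whole-series or reference-period windows);
    departures are detected with combined Shewhart and decision-interval
    CuSum control charts.  Additional tools cover Mann-Kendall trend
    tests, chronologically constrained clustering for breakpoint
    detection, variance-shift F-tests, logistic models predicting
    in/out-of-reference state with AIC subset selection and
    variance-inflation screening, and a two-dimensional
    mean-size/total-stock (MSTS) status classification.  A synthetic
    community generator with known trends, regime shifts and gaps
    supports testing and calibration without access to national
    monitoring databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
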