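Package: metarange
Title: Sensitivity Analysis and Publication-Bias Triangulation for
    Correlation Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for assessing the robustness of
    meta-analytic mean correlations, built around the personnel-selection
    use case of validity generalization. Provides Fisher-z based
    fixed-/random-effects pooling with heterogeneity and prediction
    intervals, one-sample-removed and leave-one-out influence
    diagnostics, a battery of seven publication-bias procedures
    (contour-enhanced funnel data, Duval-Tweedie trim-and-fill,
    a-priori step-function selection models with Vevea-Woods weights,
    PET-PEESE meta-regression, p-uniform, the test of excess
    significance, and cumulative meta-analysis by precision), and a
    triangulation layer that condenses the resulting set of adjusted
    estimates into baseline and maximum range statistics with
    negligible/moderate/large classifications. A synthetic-data module
    generates correlation corpora under one-tailed step-function
    publication suppression so the whole pipeline can be exercised and
    validated on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
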