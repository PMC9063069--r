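Package: telopipe
Title: Leukocyte Telomere Length Quantification and Pregnancy Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for relative leukocyte telomere length (LTL)
    measurement by quantitative PCR and its downstream epidemiological
    analysis. Converts plate-well Cq tables to T/S ratios via standard-curve
    quantification with Dixon's Q triplicate quality control, applies
    control-DNA batch adjustment and a duplicate concordance rule, assigns
    gestational timepoints and runs paired nonparametric longitudinal
    comparisons and delivery-mode regression, and screens a mixed-type
    perceived-stress survey against LTL with type-dispatched univariate
    tests, a t-SNE correlation network, and cross-validated support-vector
    prediction. Includes a synthetic plate/cohort generator with planted
    effects so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rtsne,
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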