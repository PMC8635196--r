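Package: oliveauth
Title: Chemometric Authentication of Extra-Virgin Olive Oil from
    Multielement Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating extra-virgin olive oil (EVOO) from
    multielement (ICP-MS) concentration profiles and antioxidant assay data.
    Implements censoring-aware preprocessing of detection-limited element
    tables (MDL/2 substitution, replicate averaging, detection-rate
    filtering), nonparametric group comparison (Kruskal-Wallis with Dunn
    post-hoc), DPPH radical-scavenging percentages, a from-scratch two-class
    PLS-DA classifier with an LDA-derived decision threshold, and repeated
    double cross-validation (rDCV) yielding confidence intervals for figures
    of merit, per-sample canonical scores, and model parameters. A synthetic
    data generator emulates the statistical structure of multielement EVOO
    surveys so the full pipeline is testable without access to raw data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
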