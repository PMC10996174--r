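Package: edgentropy
Title: Edge-Based Relative Entropy for Critical-Transition Detection in
    Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts a gene-expression cohort (a reference cohort plus
    staged case cohorts) and an undirected gene-interaction network into
    per-edge, per-sample relative-entropy scores built from univariate
    Gaussian kernel density estimates, aggregates them into per-sample and
    per-stage network entropy signals, flags the critical (pre-transition)
    stage with a one-sample t-test rule, and calls positive/negative
    prognostic edge biomarkers from survival-group prevalence of high-entropy
    edges. Includes a seeded synthetic-cohort generator with a planted
    critical stage and planted prognostic edges so the whole pipeline is
    testable without external data, plus delimited-text readers/writers and a
    command-line interface.
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
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
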