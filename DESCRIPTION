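Package: isostage
Title: Residential Isolation Indices and Multilevel Models of Late-Stage
    Cancer Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how residential racial/ethnic segregation
    relates to late-stage cancer diagnosis. Computes tract-based county
    Isolation Indices and flags hyper-segregated counties, applies
    registry-style cohort exclusions, attaches place-centered and
    person-centered segregation exposures, fits three-level
    random-intercept logistic models (persons within counties within
    states) by nested adaptive Gauss-Hermite quadrature, and screens
    county-level observed-minus-predicted differences for spatial
    autocorrelation with a permutation Moran's I test. A hierarchical
    cohort simulator with known truth supports end-to-end validation of
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
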