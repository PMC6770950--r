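Package: rennetpat
Title: Process Monitoring of Milk Renneting from Time-Resolved NIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for in-line monitoring of enzymatic milk coagulation
    (renneting) from time-resolved near-infrared absorbance spectra.
    Implements standard normal variate preprocessing, principal component
    rank selection, SIMPLISMA pure-spectrum initialization, multivariate
    curve resolution by alternating least squares (MCR-ALS) with
    non-negativity and unimodality constraints, extraction of the sol-gel
    transition time from resolved concentration profiles, sigmoid modelling
    of rheological time-curing curves with derivative critical times, and
    PCA-based multivariate statistical process control charts (Hotelling T2
    and Q residual statistics) for early detection of coagulation faults.
    A synthetic-data generator produces renneting batches with the rank-3
    bilinear structure the analysis assumes, including fault archetypes,
    for validation and simulation studies.
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
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
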