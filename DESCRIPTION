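Package: hookdetect
Title: Automated Detection of Hook Effect-Bearing qPCR Amplification Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hook effects (a cycle-to-cycle fluorescence decrease in
    the plateau phase) in quantitative real-time PCR amplification curves.
    Implements a linear detector that regresses the post-maximum tail and
    tests the slope with a one-sided t-test and confidence interval, a
    nonlinear detector that fits a six-parameter log-logistic model and
    tests the sign of its linear drift parameter, and their logical OR
    combination. Reads plate data from RDML (zipped or bare XML, v1.1/v1.2)
    and delimited text, simulates labelled synthetic plates spanning
    sigmoidal, hook-bearing, no-plateau and negative reaction shapes, and
    benchmarks calls against human ratings with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    digest,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
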