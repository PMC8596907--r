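Package: cqman
Title: Quantification-Cycle Analysis of qPCR Amplification Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sigmoid (modified Gompertz) model fitting for raw real-time PCR
    fluorescence curves, with analytic location of the second-derivative
    maximum, derivation of a per-reaction quantification threshold and cycle,
    single-reaction amplification-efficiency estimation from the exponential
    phase, and back-calculation of the initial target quantity. Includes a
    six-indicator evaluation suite (bias, relative error, coefficient of
    variation, precision, resolution, and Friedman rank synthesis) for
    comparing curve-analysis methods on dilution-series data, and a
    mechanistic per-cycle kinetics simulator that generates dilution-series
    plates with known ground truth.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
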