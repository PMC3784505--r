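Package: vibrisim
Title: Salience-Map Control of Whisker and Head Movements in a Simulated Rat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A closed-loop two-dimensional simulator of rat active whisker
    sensing in which a head-centric salience map, driven by whisker contact
    and a stochastic non-tactile channel and shaped by obstacle inhibition
    and inhibition of return, sets per-whisker maximum protraction angles
    and the target of head foveation. Includes a quasistatic whisker bending
    model against oriented rectangular obstacles, minimum-jerk head
    orienting, an 8 Hz whisking pattern generator, and the analysis
    pipelines for three simulated behavioural experiments: head-turning
    asymmetry, contact-induced asymmetry, and whisker spread reduction
    during wall approach. Simulation logs are returned as tibbles; results
    carry broom-style tidy() and glance() methods and ggplot2 autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
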