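Package: cuspra
Title: Cusp-Catastrophe Resilience Assessment for Ecological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the stochastic cusp catastrophe model to a state-variable
    time series driven by two external drivers (an asymmetry driver such as
    fishing pressure and a bifurcation driver such as temperature), evaluates
    the fit against a linear alternative with a four-criterion adequacy gate,
    and converts each observation's position relative to the cusp bifurcation
    set into a resilience indicator between 0 (close to a tipping point) and
    1 (far from it). Includes a simulation toolkit for generating cusp
    stochastic-differential-equation ensembles and chaotic, periodic and
    random null series, and the classification and hypothesis experiments
    that validate the adequacy gate and the indicator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
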