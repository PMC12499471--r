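Package: supercoolr
Title: Nucleation Statistics and Scale-Up Prediction for Supercooling
    Preservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for quasi-homogeneous supercooling
    preservation of biological samples. Implements classical nucleation
    theory on nano-confined icephobic patches (critical radius, spherical-cap
    barrier factors, the confined-patch transition), and a non-homogeneous
    Poisson model of stochastic ice nucleation: Weibull survival of linear
    cooling-ramp freezing assays, maximum-likelihood fitting of a power-law
    nucleation rate from small-sample assays with right-censoring, analytic
    scale-up of the expected supercooling degree with preserver surface area,
    isothermal preservation-time and freezing-probability prediction, Monte
    Carlo simulation of freezing assays and thermocouple traces, and
    recalescence-jump event detection in temperature logs.
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
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
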