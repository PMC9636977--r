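Package: netTTE
Title: Total Treatment Effect Estimation Under Unknown Network Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based estimation of the total treatment effect (TTE) of a
    randomized experiment when outcomes interfere along an unknown directed
    network. Implements the heterogeneous additive network effects (HANE)
    potential-outcomes model, the reduction of linear contagion (peer-effects)
    models to HANE form, standard randomized designs (Bernoulli, completely
    randomized, cluster-randomized, saturation) with exact treatment-moment
    calculators, the class of individually weighted linear estimators including
    the Horvitz-Thompson form and baseline-adjusted estimators, and closed-form
    bias and variance expressions for these estimators under each design.
    Every closed form is certified against an exhaustive-enumeration oracle on
    small instances and a seeded Monte-Carlo harness on larger ones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
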