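Package: sxm
Type: Package
Title: Substrate-Explicit Modeling of Organic Matter Oxidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts molecular formulae of organic compounds (such as
    FTICR-MS assigned CHNOPS formulae) into balanced oxidative-degradation
    reactions, per-compound thermodynamic profiles built on the nominal
    oxidation state of carbon (NOSC) and the thermodynamic electron
    equivalents model (TEEM), two-parameter exponential growth kinetics,
    and dynamic batch simulations with optional cybernetic enzyme
    regulation and multi-guild extensions. Ships seeded generators of
    synthetic formula tables and cohorts so every analysis is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
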