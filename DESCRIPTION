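Package: rolesim
Title: Agent-Based Simulation of Occupational Segregation by Group Type
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a scarcity-priced role economy in which agents of two
    arbitrary "types" choose occupations using prior beliefs about group
    differences, social counts of who performs or has abandoned each role,
    and their own experienced ability. Provides six states of reality
    (large, small, absent, and vanishing true type differences, with and
    without forced exploration), five shared prior regimes plus a
    perfect-knowledge baseline, configurable switching thresholds, a
    weighted-deviation segregation index, replicated experiment grids with
    seeded random-number streams, and effect-size calibration audits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
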