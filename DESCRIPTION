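Package: rpslattice
Title: Stochastic Lattice Rock-Paper-Scissors with Territorial Awareness
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo simulator for the three-species cyclic
    (rock-paper-scissors) game on a periodic square lattice in which each
    species is split into two territorial genera and intraspecific
    competition fires only across the territorial divide, at a rate scaled
    by a sensitivity coefficient k. Provides the event kernel (interspecific
    predation, territory-sensitive intraspecific competition, reproduction,
    migration), survival-state classification, two extinction-time
    definitions for the low- and high-mobility regimes, an interface-width
    statistic quantifying interpenetration of the two territories, and a
    replicated sweep harness with standard-error aggregation for mobility
    and sensitivity scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
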