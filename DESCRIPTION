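Package: resilsim
Title: Stochastic Simulation of Breeding Programmes for Weather
    Resilience in Dairy Sheep and Goats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward stochastic simulation of closed dairy goat and sheep
    breeding programmes under the infinitesimal model, for evaluating
    selection indices that trade production traits off against weather
    resilience (the slope of milk or protein yield on ambient
    temperature). Populations of true breeding values and environmental
    deviations are propagated across non-overlapping generations with
    Mendelian sampling, pedigree inbreeding and truncation selection on a
    weighted index of standardized pseudo-estimated breeding values.
    Scenarios differing in the selection emphasis placed on resilience are
    compared through realized genetic gains, a standardized progress index
    and economic profit under current and warmed (+1 and +2 degree
    Celsius) climates. Ships calibrated parameter sets for an Atlantic
    dairy goat and a Mediterranean dairy sheep programme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
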