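Package: pulseCR
Title: Microbial Community Assembly Under Continuous and Pulsed Resource
    Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation pipeline for classical Monod consumer-resource
    competition under contrasting resource supply dynamics: continuous
    (chemostat) supply versus discrete resource pulses with cell transfer
    at fixed intervals (serial-batch culture), with total resource flux
    and mortality held constant across pulsing intervals.  Includes
    randomised trait sampling with an optional gleaner-opportunist
    trade-off between maximum growth rate and substrate affinity,
    compositional-overlap (Jaccard) and abundance-weighted trait summaries
    across pulsing intervals, local stability analysis at the
    continuous-supply steady state, and a reproducible, seed-provenanced
    experiment orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
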