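Package: stoopsim
Title: Physics-Based Simulation of Falcon Stoops on Maneuvering Prey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based, three-dimensional flight simulator for aerial
    predator-prey engagements between a peregrine falcon and a starling-like
    prey bird. Flapping and gliding flight are modelled with a quasi-steady,
    wingbeat-averaged aerodynamic force law with physiological torque limits
    and optimal wing retraction; the attacker is guided by pure proportional
    navigation acting on a noisy, sampled line-of-sight, and banks to turn
    using minimum-time (bang-bang) roll control. The package provides flight
    performance envelopes, single-engagement simulation with catch /
    near-miss / timeout classification, Monte-Carlo sweeps over attack
    strategies, and generalized-additive-model response surfaces of catch
    success over the strategy space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    generics,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
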