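Package: socialbalance
Title: Coevolutionary Opinion and Signed-Network Dynamics under Social Balance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator for a coevolutionary model of opinion
    formation on signed social networks. Binary opinions and friendly or
    hostile ties evolve by Metropolis dynamics on a social-stress
    Hamiltonian that combines a homophily term, a Heider triadic-balance
    term, and an optional exogenous pro-social field. The package builds
    regular ring lattices, small-world and adaptively rewired topologies,
    tracks order parameters (triangle balance index, relative stress,
    opinion alignment), detects echo chambers through frustration-minimizing
    signed-graph partitioning, and ships experiment drivers for
    phase-diagram scans, hysteresis sweeps, external-field scans and
    convergence-time distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
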