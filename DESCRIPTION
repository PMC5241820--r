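Package: ideapop
Title: Stochastic Evolutionary Dynamics in Finite Populations of Ideas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents reinforcement learning in repeated 2x2 games as a
    birth-death process in finite populations of ideas. Builds exact
    transition rates from an entropically modified fitness (payoff minus
    memory-loss times log-frequency), simulates the resulting one- and
    two-population Markov chains with the Gillespie algorithm, computes
    fixation probabilities and mean fixation times in closed form and by
    backward-master-equation linear solves, and analyses the deterministic
    Sato-Crutchfield, replicator and replicator-mutator limits, including
    fixed-point classification and saddle-node bifurcation scans over the
    memory-loss parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
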