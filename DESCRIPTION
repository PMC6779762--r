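Package: decodecap
Title: Channel Capacity of Signaling-Pathway Decoding Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic and deterministic modelling of how a signaling
    pathway's decoding section turns a transient kinase input into gene
    expression, and how much information survives the trip. Provides exact
    Gillespie-type simulation (Ogata thinning for the time-inhomogeneous
    input hazards, optional piecewise-constant lognormal extrinsic noise on
    a kinetic parameter), mean-field ODE integration for validation,
    histogram channel estimation, Arimoto-Blahut channel capacity,
    multivariate mutual information under conditional independence, and
    coefficient-of-variation readouts. Ships the MAPK/ERK decoding-section
    model, a steady-state-normalized minimal feed-forward-loop decoder, a
    linear-chain control, two-state promoter reporter genes, analytic
    channel fixtures, and config-driven drivers for the five in-silico
    experiments built on them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
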