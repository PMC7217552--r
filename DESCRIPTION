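Package: hetSIS
Title: SIS Epidemics with Heterogeneous Recovery Rates on Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the susceptible-infected-susceptible (SIS)
    epidemic model when each node carries its own recovery rate. Provides
    network substrates (Erdos-Renyi, uncorrelated configuration-model
    power-law graphs, edge-list input), recovery-rate schemes (inverse-gamma,
    degree-correlated, power-law shuffled), the quenched mean-field spectral
    theory built on the contact matrix Q = D^-1 (A o W) whose leading
    eigenvalue sets the epidemic threshold, an exact continuous-time
    Gillespie simulator with quasistationary sampling yielding the order
    parameter and susceptibility, a brute-force quasistationary oracle for
    tiny graphs, and experiment drivers for susceptibility sweeps, shape
    scans and finite-size analyses of structure-dynamics correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    Rcpp,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
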