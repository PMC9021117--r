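Package: ctdyn
Title: Continuous-Time Dynamical Network Analysis of Intensive
    Longitudinal Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing multivariate psychological (and other)
    time series as continuous-time dynamical networks. Fits the
    continuous-time first-order vector autoregression (the multivariate
    Ornstein-Uhlenbeck process) to irregularly sampled data by maximum
    likelihood, maps drift matrices to lagged-parameter matrices at any
    time-interval via the matrix exponential, computes time-interval-resolved
    total, direct and indirect effects defined through pulse and press
    interventions, and derives intervention-oriented centrality measures
    (total effect centrality and indirect effect centrality) alongside the
    classical discrete-time measures (expected influence, out-strength,
    betweenness). Includes exact stochastic simulation of the process on
    arbitrary sampling schedules, an experience-sampling beep-schedule
    generator, intervention trajectory simulation, likelihood-based
    uncertainty bands, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
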