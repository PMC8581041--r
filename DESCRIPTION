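Package: decisionscape
Title: Attractor Landscapes, Probability Flux and Transition Kinetics for
    Spiking Decision Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a biophysically grounded two-choice decision circuit of
    leaky integrate-and-fire neurons with conductance-based AMPA, NMDA and
    GABA synapses, and quantifies its stochastic dynamics through the
    non-equilibrium potential landscape U = -ln(Pss) over population firing
    rates, coarse-grained probability flux fields, barrier heights between
    attractors, transition-path averaging and mean first-passage times.
    Includes seeded two-dimensional Langevin surrogates (double well, triple
    well, rotational Ornstein-Uhlenbeck) with analytic stationary laws, flux
    fields and quadrature first-passage references, so every estimator can be
    validated against closed forms without long network simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
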