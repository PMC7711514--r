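Package: entroprod
Title: Entropy Production Rates for Exactly Solvable Stochastic Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and simulated entropy production rates for
    continuous-time Markov chains, one-dimensional diffusions and mixed
    discrete-continuous processes. Provides a generic master-equation
    engine with the internal/external and adiabatic/non-adiabatic
    decompositions of the entropy rate, closed-form calculators for a
    catalogue of solvable systems (two- and three-state chains, complete
    graphs, many-particle occupation processes, lattice and ring random
    walks, drift-diffusion, the driven Ornstein-Uhlenbeck process, ring
    diffusion in a periodic potential, run-and-tumble and switching
    diffusion), and stochastic simulators (Gillespie, Euler-Maruyama)
    whose trajectory-level estimators converge to the analytic rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
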