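Package: kmclearn
Title: Learning and Reducing Kinetic Monte Carlo Models of Reactive
    Chemistry from Bond Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers stochastic chemical reaction networks (kinetic Monte
    Carlo / chemical master equation models) from per-frame bond graphs of
    reactive atomistic trajectories. Bonding states are smoothed with a
    bond-duration hysteresis criterion, molecules are identified as
    connected components of the bond graph, and reaction events are
    extracted from changes between consecutive frames. Rate coefficients
    are estimated in closed form by maximum likelihood under the
    tau-leaping Poisson observation model, and learned networks are
    simulated exactly with the Gillespie stochastic simulation algorithm.
    The package also reduces learned networks by observed-count filtering,
    by an exact integer quadratic program matching conditional moments of
    concentration changes, and by its box-constrained LASSO relaxation
    with epsilon-thresholding. A synthetic-data module generates noisy
    bond signals, atom-resolved reacting trajectories from known networks,
    and Poisson count streams for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
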