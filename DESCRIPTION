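Package: hybridsim
Title: Hybrid Stochastic-Deterministic Simulation of ODE-Defined Biochemical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven hybrid simulation of biochemical models defined only
    by their ordinary differential equations. A deterministic pre-simulation
    extracts per-species trajectory features, a calibrated random-forest
    classifier partitions species into stochastic and deterministic regimes,
    and a piecewise-deterministic engine couples birth-death stochastic
    updates (with propensities derived from a production-degradation split of
    the ODE drift) to stiff ODE integration. Includes a concentration-to-count
    adapter, a seeded generator of synthetic training models, and reference
    solvers (exact Gillespie SSA, tau-leaping, Haseltine-Rawlings hybrid,
    pure ODE) with benchmark statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
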