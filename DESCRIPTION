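Package: crimedyn
Title: Compartmental Dynamics of Crime, Incarceration and Recidivism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic compartmental models of the spread of criminal
    activity through social contagion, with incarceration, release,
    recidivism and redemption flows. Implements a hierarchy of three-,
    five- and nine-compartment ordinary differential equation systems,
    closed-form basic reproduction ratios (tipping points) and their
    parameter sensitivities, endemic equilibria and the 1/R0 street
    prevalence law, constructive linear Lyapunov certificates for global
    stability of the crime-free state, phase-plane classification of the
    planar reductions, and policy experiments (prison term length sweeps,
    parole elimination, three-strike sentencing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
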