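Package: coarsegame
Title: Game-Theoretic Analysis of Empirical Antibiotic Prescribing and
    Information Coarsening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models empirical antibiotic prescribing as a two-physician
    stochastic game over a depletable pool of antibiotic effectiveness.
    Provides signal distributions for the posterior probability of
    bacterial infection, single-patient treatment-threshold analysis,
    recursive value computations, backward-induction solvers for the
    symmetric Markov perfect equilibrium and the socially optimal policy,
    a Monte Carlo simulator of the repeated game, and tools for
    dichotomizing ("coarsening") a continuous infection-probability
    signal at a threshold, including the stability condition under which
    treating only high-signal patients is an equilibrium. A synthetic
    cohort generator emulates a pediatric respiratory-infection setting
    for end-to-end pipeline checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
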