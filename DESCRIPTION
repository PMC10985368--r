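Package: srdmsim
Title: Individual-Based Simulation of Feminising Sex-Ratio-Distorting
    Microbes in Variable Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based, daily-cycle simulation of arthropod host
    populations infected by maternally inherited feminising microbes
    (e.g. Wolbachia-like sex-ratio distorters). Adults die according to
    phenotype-environment mismatch, females are located by questing males
    at a sex-ratio-dependent daily rate, infected mothers transmit the
    microbe vertically and infected offspring develop as females, and
    juveniles suffer density-dependent mortality between non-overlapping
    generations. The package provides the elementary stochastic rate
    functions, the season/generation simulator, four analysis protocols
    (ecological trajectories, Latin-hypercube sensitivity analysis of
    extinction risk with logistic-GLM surfaces, a mechanistic growth-rate
    analysis against abundance and operational sex ratio, and a
    phenotypic-evolution-rate analysis), and a command-line interface for
    reproducible experiment runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
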