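Package: fepcycles
Title: Alchemical Free-Energy Estimation, Thermodynamic Cycles, and ITC
    Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for stratified alchemical free-energy perturbation (FEP)
    analysis of mutation-induced changes in ligand binding, built around the
    cation-binding pocket of the melibiose permease MelB.  Provides
    lambda-window sampling of analytically solvable toy Hamiltonians by
    Metropolis Monte Carlo, free-energy estimators over forward/backward
    window pairs (exponential averaging, simple overlap sampling, Bennett
    acceptance ratio) with bootstrap errors and overlap diagnostics,
    thermodynamic-cycle algebra for relative binding free energies and their
    conversion to pKa shifts, one-site isothermal titration calorimetry
    (ITC) simulation and fitting with dilution-heat subtraction and
    cooperativity folds, plus readers and writers for per-window energy
    difference files and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
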