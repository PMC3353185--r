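Package: gynosim
Title: Population Dynamics of Mixed Sexual and Gynogenetic Reproduction in
    Fluctuating Environments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward-time, individual-based simulation of two sympatric
    diploid fish populations that reproduce by a mixture of sexual
    reproduction and gynogenesis (sperm-dependent parthenogenesis) and
    compete for L binary environmental resources under periodic
    environmental fluctuation. Genotype fitness follows multiplicative
    per-locus match scores mapped through a Gaussian stabilizing-selection
    function; viability selection uses a modified Beverton-Holt model with
    genotype-specific carrying capacities coupled across the two
    populations. Provides an exact genotype-class count engine (with a
    per-individual reference engine), competition-tournament, adaptation
    and stability-period experiment harnesses, and a deterministic
    two-class (fit/unfit) companion recursion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'fitness.R'
    'population.R'
    'dynamics.R'
    'engine.R'
    'individuals-engine.R'
    'experiments.R'
    'deterministic.R'
    'config.R'
    'gynosim-package.R'
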