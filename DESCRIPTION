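Package: cofactorflux
Title: Constraint-Based Modelling of Non-Consumed Ion Cofactors in
    Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("cofactorflux", "developers", email = "cofactorflux@example.org",
           role = c("aut", "cre"))
Description: Tools for representing iron-family cofactors (ionic iron, haems,
    iron-sulphur clusters) in genome-scale stoichiometric models and for
    estimating the metabolic requirement of cofactor-recruiting enzymes by
    linear programming.  Provides SBML input/output (Level 2 COBRA notes and
    Level 3 fbc dialects), flux balance and flux variability analysis with a
    built-in bounded-variable simplex solver, cofactor augmentation of
    catalysed reactions with free/spent pool accounting, pseudo-metabolite
    circuits for scaffold-based iron-sulphur cluster biogenesis and for the
    iron regulon, biomass cofactor coefficient derivation from amino-acid
    binding ratios, in-silico gene essentiality evaluation with confusion
    matrix metrics, environmental and genetic perturbation analysis with
    flux-rewiring classification, and coefficient sweeps for cofactor
    turnover estimation.  A deterministic miniature iron-metabolism fixture
    generator with analytically known optima supports desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
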