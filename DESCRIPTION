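Package: thermoflux
Title: Constraint-Based Modelling of Thermophilic Ethanologen Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based analysis of fermentative metabolism in the
    thermophilic ethanologen Thermoanaerobacterium saccharolyticum. Provides
    an S4 data model for stoichiometric networks with gene-protein-reaction
    rules and native JSON/TSV (plus SBML-subset) input/output, a
    bounded-variable simplex solver for flux balance analysis and flux
    variability analysis, phenotypic phase planes and production envelopes,
    a strong-duality bilevel knockout-design optimizer for growth-coupled
    product formation with an exhaustive-search oracle, a minimal-additions
    gap filler, a curated core model of T. saccharolyticum central
    fermentative metabolism with hydrogenase constraints and engineered
    strain constructors, and seeded generators of synthetic networks with
    analytically known optima.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
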