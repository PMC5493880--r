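Package: mustflux
Title: Constraint-Based Metabolic Modeling with FBA, FVA and MUST-Set Strain Design
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and simulating genome-scale
    stoichiometric metabolic models of the kind used for Corynebacterium
    glutamicum strain engineering. Provides a tabular and SBML-subset model
    reader/writer with gene-protein-reaction (GPR) boolean logic,
    reconstruction quality control (elemental and charge balance, biomass
    molecular weight, Gibbs-energy based reaction directionality), a
    linear-programming engine for flux balance analysis (FBA), total-flux
    minimization at the optimum, flux variability analysis (FVA), gene
    knockout simulation, robustness scans and cofactor accounting, and the
    MUST stage of the OptForce strain-design procedure which classifies
    reactions into MustU/MustL/MustX intervention sets by comparing
    wild-type flux spans (under 13C-derived bounds) against
    forced-overproduction flux spans. Ships synthetic model generators,
    including a mass- and charge-balanced mini central-carbon model with
    lysine and proline branches, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
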