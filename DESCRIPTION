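Package: SalinaCore
Title: Constraint-Based Analysis of the Dunaliella salina Carbon-Core
    Metabolic Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartmentalized stoichiometric network modelling and flux
    balance analysis (FBA) for the carbon-core metabolism of the halotolerant
    green microalga Dunaliella salina. Provides S4 containers for
    stoichiometric networks with compartments, exchange reactions and flux
    bounds; SBML and delimited-table import/export; structural and
    feasibility diagnostics (blocked reactions, dead-end metabolites,
    infeasibility localisation); a linear-programming FBA engine with single
    and lexicographic (ordered multi-objective) maximisation, e.g. growth
    first and beta-carotene second; a scenario runner for light-by-nutrient
    uptake scenarios; and synthetic network generators (a three-compartment
    toy phototroph with closed-form optima, and random sparse networks) so
    every component is testable without external model files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'lp.R'
    'network.R'
    'bounds.R'
    'validate.R'
    'equation.R'
    'sbml.R'
    'tables-io.R'
    'consistency.R'
    'fba.R'
    'scenarios.R'
    'synthetic.R'
    'cli.R'
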