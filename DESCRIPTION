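Package: pathmapr
Title: Integrative Mapping of Linear Metabolic Pathways from Heterogeneous Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the order of enzymes and metabolites in linear metabolic
    pathways by combining heterogeneous evidence (virtual-screening docking
    scores, ligand-set similarity E-values, generic SMIRKS reaction
    transforms, thermal-shift screening hits, homology to characterized
    enzymes, genome context, and central-metabolism pathway boundaries) into
    a single Z-score restraint function, and searching the combinatorial
    space of candidate pathway models by Metropolis Monte Carlo simulated
    annealing. The resulting ensemble of good-scoring models is clustered by
    Hamming distance, summarized as enzyme-ligand edge frequencies, checked
    for sampling convergence, and exported as a union-network JSON document.
    A planted-pathway synthetic problem generator makes the whole stack
    testable end to end. Morgan fingerprints, SMIRKS application and
    stereoisomer enumeration are delegated to RDKit through a bundled
    Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on the PATH
Config/testthat/edition: 3
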