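Package: porekit
Title: Desk-Scale Structural Pipeline for Nuclear Pore Complexes
Version: 0.1.0
Authors@R:
    person("porekit", "maintainers", email = "porekit@example.org", role = c("aut", "cre"))
Description: Tools for analysing eightfold-symmetric nuclear pore complexes
    (NPCs) at desk scale: synthetic generation of C8 ring complexes, noisy
    missing-wedge subtomograms, subunit coordinate tables and replicate
    peptide tables; subtomogram alignment, wedge-compensated averaging,
    symmetry expansion and Fourier shell correlation; pore centre and
    diameter estimation from subunit coordinates; composite scaffold
    assembly with stoichiometry accounting; multi-restraint rigid-body
    simulated-annealing refinement against density maps; Kabsch
    superposition and TM-score structure comparison; and emPAI-based
    nucleoporin inventories from peptide detection tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
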