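Package: spindock
Title: Rigid-Body Protein Docking with PELDOR/DEER Spin-Label Distance Restraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Docks rigid protein bodies using pulsed electron-electron resonance
    (PELDOR/DEER) inter-spin-label distances. Generates nitroxide spin-label
    conformer ensembles at engineered cysteine sites (R1 accessible-volume
    rotamer search, Rx2 two-anchor constrained sampling), evaluates ensemble
    R^-3-averaged square-well distance restraints, non-crystallographic
    symmetry (NCS) restraints over equivalence groups, and a scalable
    soft-repulsion non-bonded term, then minimises rigid-group poses through a
    staged protocol and refines interface side-chain torsions with rigid ring
    moieties. Includes a synthetic-fixture generator (toy helical dimers,
    planted symmetric tetramers, restraint tables) and XPLOR-style energy
    reporting, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
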