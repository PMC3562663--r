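Package: topper
Title: Evidential Fusion of Transmembrane Protein Topology Predictors
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Combines per-residue transmembrane-topology predictions from
    several individual predictors into a consensus topology using
    Dempster-Shafer evidential reasoning (the TOPPER method). Each predictor's
    confusion matrix is turned into class-conditioned basic probability
    assignments, per-residue evidence is fused with Dempster's rule of
    combination, and the fused mass function is decided through the pignistic
    probability transformation. Includes decoding of residue labels into
    topology models (transmembrane segments plus N-terminal orientation),
    evaluation at residue, segment and topology level (recall/precision/F,
    the Tusnady-Simon M/C/Q segment-overlap scores, topology accuracy), a
    seeded tenfold cross-validation harness, readers and writers for FASTA,
    per-residue label files and confusion-matrix tables, and a synthetic
    benchmark generator with known noise structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
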