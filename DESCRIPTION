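Package: flexwobble
Title: Structural Flexibility and Secondary-Structure Wobble Analysis of
    Protein Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the conformational flexibility of groups of protein
    crystal structures sharing (near-)identical sequences. Superposes backbone
    C-alpha traces (Kabsch least squares, TM-score, an iterative
    structure-based aligner), assigns secondary structure with a simplified
    Kabsch-Sander method or reads classic DSSP output, detects
    secondary-structure wobble sites and their helix/sheet/coil transition
    types, classifies alignment sites (common/multi/gap) across all
    structure-pair alignments of a group pair, scores structure-derived
    sequence alignments with a BLOSUM62 evolutionary distance, and analyses
    gap openings/extensions of alignments that violate the
    lower-RMSD-lower-distance expectation. Includes a deterministic synthetic
    ensemble generator with known hinge, wobble and mutation ground truth so
    the whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
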