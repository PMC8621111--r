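Package: fibrilkit
Title: Symmetry Scoring, Assembly and Geometric Characterization of
    Amyloid Fibril Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and characterizing structural models of
    amyloid fibrils from short protofilament stacks. Scores multi-chain
    protofilament models by translational symmetry using the
    peptide-chain-average RMSD (pcaRMSD), assembles long fibrils from a
    protofilament by iterated overlap superposition, and measures fibril
    observables: length, per-interface twist angle, rise and helical
    pitch, plus Kabsch-Sander backbone hydrogen bonds and beta-sheet
    residue content. Includes proper-rotation Kabsch superposition, RMSD
    matrices and centroid selection for conformer ensembles, a synthetic
    helical-fibril generator with full backbones for validation, and
    generation of inter-chain distance-restraint tables for
    coarse-grained peptide docking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
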