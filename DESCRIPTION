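Package: ligfunnel
Title: Multi-Step Ligand-Based Virtual Screening Funnel
Version: 0.1.0
Authors@R: person("Screening", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for ligand-based virtual screening of small-molecule
    libraries against G-protein-coupled receptor targets. Implements activity
    data curation (pKi threshold labeling, stratified 7:2:1 splitting,
    clustering of potent actives to representatives, property-matched decoy
    selection), circular (ECFP4-style) bit fingerprints and Tanimoto
    similarity, two trainable classifiers (a dense network on fingerprint bits
    and a graph-convolutional neural-fingerprint network), ligand-based 3D
    pharmacophore hypothesis generation and k-of-n partial-match screening,
    early-recognition enrichment metrics (EF, BEDROC, ROC, AUAC), and a
    three-stage screening funnel (classifier consensus, pharmacophore filter,
    cascade percentage filtering over externally produced docking scores) with
    Tanimoto novelty annotation. Includes generators for fully synthetic test
    libraries so every stage is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
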