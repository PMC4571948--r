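Package: ARBmotif
Title: Scanning and Prioritization of Ankyrin-Repeat-Binding ZDHHC17/13 Motifs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the short linear motif recognized by the ankyrin repeat
    domain of the S-acyltransferases zDHHC17 and zDHHC13. Implements the
    position-class grammar of the [VIAP][VIT]XXQP consensus and its three
    submotifs, scanning of protein sequences with configurable residue
    numbering, in-silico point mutagenesis with motif-integrity calls,
    cross-species motif conservation through pairwise global alignment
    (BLOSUM62, affine gaps), an intrinsic-disorder filter with two-track
    rescue logic, the staged candidate-prioritization cascade, neighbor-
    joining trees of ankyrin-repeat-containing zDHHC enzymes, and seeded
    synthetic-data generators with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Phylogenetics, MotifDiscovery
RoxygenNote: 7.3.3
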