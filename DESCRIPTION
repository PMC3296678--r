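Package: intronevo
Title: Inference of Intron Gain and Loss Events and Their Molecular Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying spliceosomal intron turnover in groups of
    closely related genomes. Ortholog groups are detected by reciprocal best
    hits over Smith-Waterman local alignments, intron positions are made
    comparable across species by inserting fixed-length artificial intron
    markers into coding sequences before progressive multiple alignment, and
    gain and loss events are called on a species tree by Dollo parsimony with
    outgroup polarization and annotation-error quality controls. Accepted
    events are then scanned for mechanistic signatures: transposon insertion
    with target-site duplications, double-strand-break repair using
    mitochondrial filler DNA (with a sequence-shuffling null), imprecise
    deletion by non-homologous end joining, reverse-transcriptase-mediated
    loss biases (positional, germline-expression and adjacent-loss tests),
    and intron sliding. A forward simulator of gene-family evolution with
    mechanism-labelled events provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
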