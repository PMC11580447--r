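Package: aureomine
Title: Mining and Characterization of Aureocin A53-Like Leaderless Bacteriocins
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An in silico discovery pipeline for aureocin A53-like leaderless
    bacteriocins. Builds profile hidden Markov models from seed alignments of
    known core peptides, scores short-protein databases with a glocal forward
    algorithm, calibrates E-values on shuffled-composition null sequences, and
    runs a two-round iterative search. Mined peptides are organized with
    percent-identity sequence similarity networks, greedy identity clustering,
    physicochemical profiling (GRAVY hydropathy, molecular weight, net charge,
    isoelectric point), neighbor-joining phylogeny with outgroup rooting, and
    classification of the surrounding bacteriocin gene cluster into functional
    roles. A synthetic-data module generates peptide families at controlled
    mutational distances, decoy proteins and operon layouts with a ground-truth
    ledger so the whole pipeline is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, HiddenMarkovModel, Phylogenetics
RoxygenNote: 7.3.3
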