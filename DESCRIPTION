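Package: orfsvm
Title: Coding-Potential Classification of Open Reading Frames with
    Class-Weighted Linear Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies open reading frames (ORFs) as protein-coding or
    non-coding from nucleotide sequence alone. Six frame-aware sequence
    statistics (positional mono- and di-nucleotide frequencies, mono- and
    di-codon usage, mono- and di-amino-acid usage with stop codons treated
    as a 21st residue) are assembled into a feature vector of up to 4682
    dimensions, min-max scaled on the training set, and fed to a
    class-weighted linear support vector machine. Includes stratified
    k-fold cross-validation screening over all 63 feature-block
    combinations, grid search over the cost and class-weight-ratio
    hyperparameters, decision-threshold sweeps, dataset construction from
    a genome plus annotation (verified ORFs as positives, intergenic
    sequences longer than 300 bp as negatives), a retrospective
    annotation-snapshot coverage protocol, and a seeded synthetic-sequence
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
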