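Package: kmerBayes
Title: Naive Bayes Taxonomic Classification of Metagenomic Reads with
    Canonical K-mer Counting
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A naive Bayes taxonomic classifier for short metagenomic
    reads. Reference genomes are summarised as k-mer count tables
    (optionally canonical, i.e. strand-collapsed), stored one file per
    genome so that new genomes can be added to a database without
    recounting existing members. Query reads are scored against every
    training genome with add-one (Laplace) smoothed log-likelihoods,
    counted on the fly and evaluated in memory-bounded batches, with
    either a best-hit summary or the full read-by-genome score matrix as
    output. The package also provides per-rank micro/macro
    precision-recall evaluation with confusion matrices, a five-fold
    cross-validation harness over genome classes, rank-level relative
    abundance profiles with Bray-Curtis comparison, and a seeded
    simulator for synthetic genomes and error-bearing reads so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    parallel
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
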