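Package: glycopan
Title: Pangenome Analysis of Nucleotide-Sugar Biosynthesis Potential
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for comparative-genomics analysis of nucleotide-sugar
    (glycan precursor) biosynthesis potential across a set of related genomes,
    such as metagenome-assembled genomes of a single genus. Provides quality
    and homology-evidence screening of HMMER search results against KO-style
    profile collections, inference of pathway presence on a reference
    metabolic network (route completeness plus terminal-enzyme criteria),
    core/accessory classification of genes and nucleotide-sugars, Fitch
    small-parsimony counting of pathway gain/loss events on a marker-gene
    species tree, monophyly scoring of target sequences within gene-family
    trees, and permutation tests of median differences between the core and
    accessory groups. A synthetic-data generator with known ground truth
    makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phangorn,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
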