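Package: wgdtrace
Title: Detection, Dating and Phylogenetic Placement of Whole-Genome Duplications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers paleopolyploidy from genome data: builds redundancy-corrected
    (node-weighted) Ks age distributions of a paranome with Nei-Gojobori (NG86)
    synonymous-divergence estimates, detects co-linear segments (anchor pairs)
    by dynamic-programming chaining of gene-order matches and derives
    duplication-depth profiles, identifies reciprocal-best-hit orthologs for
    relative timing of duplication versus speciation, and places anchor-pair
    duplication events on a species tree through gene-tree reconciliation with
    bootstrap support. Ships a genome-evolution simulator (gene families along
    a species tree, WGD with partial retention, fractionation, inversions,
    codon sequences with calibrated synonymous divergence) so that every stage
    can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    phangorn,
    igraph,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, rtracklayer, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
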