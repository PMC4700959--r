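Package: popcons
Title: Detecting Selective Constraint from Population Genomic Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genomic windows as constrained or unconstrained by
    purifying selection using only within-species polymorphism. Sites are
    polarized by outgroup parsimony, a modified unfolded site frequency
    spectrum is computed in sliding windows over informative sites, and a
    soft-margin RBF support vector machine trained on conservation-labelled
    windows assigns each window a calibrated posterior probability of
    constraint. High-confidence windows are merged into popCons and popUncons
    elements, contrasted with a phylogenetic conservation track to call
    human-specific gain- and loss-of-function candidates, and tested for
    feature enrichment by constrained coordinate permutation. A forward
    Wright-Fisher simulator with selection, recombination and a two-deme
    out-of-Africa style demography supplies training corpora and synthetic
    genome bundles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    Biostrings,
    e1071,
    pROC,
    jsonlite,
    data.table
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
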