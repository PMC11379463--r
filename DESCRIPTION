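Package: CloneNMF
Title: Clonal Deconvolution of Tumour scRNA-seq from Noisy Single-Cell
    Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies cancer clonal populations and their associated
    variants from sparse, noisy single-nucleotide-variant calls in
    single-cell RNA-seq data. Per-cell allele counts (cellsnp-lite style
    VCF plus sparse AD/DP Matrix Market matrices) are discretized into a
    variant-allele-frequency observation matrix and a confidence weight
    matrix, factorized by a weighted non-negative matrix factorization
    fitted with alternating exact non-negative least squares, aggregated
    over bootstrap replicates with factor alignment, and the best variant
    subset and factor number are selected by an orthogonality score on
    the cell factors. Includes variant filtering grids, per-cell clone
    assignment with healthy/cancer factor labelling from cell-type
    priors, clone-associated variant extraction, and a synthetic-data
    generator with planted clonal structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    igraph
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
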