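Package: kpaint
Title: K-mer Sub-Region Similarity, Lineage Tracing and Copy-Number
    Analysis for Hybrid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mosaic (non-linear, admixed) ancestry in hybrid genomes
    by partitioning a reference assembly into fixed-size sub-regions, reducing
    each sub-region to a canonical k-mer set, scoring every sub-region against
    a panel of strains by k-mer containment, and tracing the top-scoring
    strains onto a MinHash/Mash-derived population tree. Also provides
    read-depth based chromosome and gene copy-number estimation with
    heterozygous-SNP filtering, and tandem-repeat copy-number estimation for
    flocculin-type genes via local alignment clustering. Includes a synthetic
    strain-panel simulator so the whole workflow can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    ape,
    stringi,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr
Config/testthat/edition: 3
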