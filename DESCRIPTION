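Package: fungidist
Title: Genomic Distance Thresholds for Fungal Species Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise k-mer based genomic distances between genome assemblies
    and fixed equal-error thresholds that separate within-species from
    between-species distances. Implements exact canonical k-mer sets with a
    capture-recapture corrected overlap statistic, bottom-s MinHash sketches
    with the Mash distance transform, HyperLogLog sketches with a
    cardinality-based Jaccard similarity, lineage-stratified enumeration of
    genome pairs at six taxonomic ranks, an equal-error-rate binary search for
    rank-separating thresholds, and a hierarchical clade simulator for
    validating the whole pipeline on genomes with known divergence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
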