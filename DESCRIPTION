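Package: famcons
Title: Family-Level Conserved-Region Scans, Genetic Diversity, and
    Convergent Amino-Acid Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomic analysis of closely related species mapped
    to a single family reference genome. Detects family-wide highly
    conserved regions (HCRs) with a sliding-window scan of jointly
    homozygous positions tested against the chromosome background
    (Fisher's exact test with Benjamini-Hochberg correction, middle-tile
    extraction), computes per-species nucleotide diversity and genetic
    distance from heterozygous and homozygous SNV counts, and classifies
    group-specific, convergent, and function-altering amino-acid changes
    from protein multiple alignments. Ships a synthetic-data generator
    that plants low-diversity intervals and diagnostic alignment columns
    so every stage can be scored against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
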