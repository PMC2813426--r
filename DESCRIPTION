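Package: breakscan
Title: Mate-Pair Structural Variant Detection and Small-Variant Filtering
    for Rearranged Cancer Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural variation from long-insert mate-pair
    sequencing by binning the genome, pairing source and destination bins
    that share aberrantly mapped read pairs ("binsets"), clustering binsets
    into breakpoint-flanking regions, and classifying intrachromosomal
    events as complete or heterozygous deletions from interior-to-flank
    read-depth ratios. Also provides duplicate-read removal, read-level
    eligibility and site-level filters for single-nucleotide variants and
    small (<21 bp) indels, dbSNP-style catalog matching, gene-model
    consequence annotation with knockout classification, and the summary
    statistics used to characterise a rearranged genome (substitution
    spectra, diversity, proximity enrichment, Monte-Carlo exon-overlap
    tests, proportion comparisons, array concordance). A synthetic diploid
    genome simulator with planted variants, deletions and translocations
    supplies truth sets so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
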