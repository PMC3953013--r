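Package: neosexscan
Title: Detection and Characterization of Neo-Sex Chromosome Evolution from
    Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for young (neo-)sex chromosomes created by
    Y-autosome fusions. Detects Y degeneration from sex-differential
    normalized read depth with iterative Grubbs outlier testing, scans
    X-Y heterozygosity and between-species divergence in sliding windows,
    classifies putatively X-specific, Y-specific and shared SNPs from
    sex- and species-stratified diploid genotypes, estimates Ka/Ks between
    virtual X and Y haplotypes and lineage-specific two-ratio dN/dS by
    Nei-Gojobori counting with parsimony branch assignment, and tests
    sex- and species-biased expression for chromosomal enrichment. Includes
    a synthetic-data generator with known per-site truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
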