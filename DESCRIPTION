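Package: regqtl
Title: QTL Mapping of Binary Perennial-Regrowth Traits in F2 Intercrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping perennial regrowth and tillering loci in F2
    intercross populations between maize and its perennial wild relative
    Zea diploperennis. Implements the two complementary mapping strategies
    used in such studies: QTL-seq bulk segregant analysis (per-SNP
    SNP-index and delta SNP-index from pooled sequencing of
    phenotype-selected bulks, summarised in 1-Mb bins) and single-marker
    binary-trait QTL scans (EM maximum likelihood LOD with genome-wide
    permutation thresholds), together with Mendelian segregation and
    two-locus linkage chi-square tests, Kosambi genetic-map estimation
    from codominant markers, crossover-parsimony quality filters, and a
    forward simulator of F2 populations, phenotype-selected bulks and
    pooled read counts written as VCF for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
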