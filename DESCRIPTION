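Package: cistrans
Title: Cis/Trans Regulatory Divergence from Allele-Specific Expression in Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes into seven cis/trans regulatory-divergence
    categories from parental and F1-hybrid allele-specific read counts,
    using exact binomial tests of allelic ratio in the F1 hybrid and an
    in-silico (read-mixed) hybrid, a Fisher exact test between the two, and
    Benjamini-Hochberg false-discovery-rate control. Assigns gene
    duplication modes (singleton, dispersed, proximal, tandem, whole-genome
    duplication) from homology hits and gene order, splits whole-genome
    duplicates into young and old age classes by k-means clustering of
    per-block synonymous substitution rates, cross-tabulates regulatory
    categories against duplication modes with chi-squared comparisons, and
    performs one-tailed hypergeometric term over-representation analysis.
    Includes a synthetic-data generator producing allele-count, variant,
    gene-model and homology fixtures with known regulatory architectures so
    the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
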