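Package: haplopart
Title: Multi-Allelic Haplotype Partition, GBLUP and EM-GREML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats each haplotype within a haplotype block as an allele of a
    multi-allelic locus and partitions its genotypic values into additive
    (breeding) and dominance values under Hardy-Weinberg equilibrium. Provides
    the closed-form factorization of additive and dominance values into
    frequency-dependent coding matrices and effect vectors, haplotype and
    single-SNP genomic additive and dominance relationship matrices, genomic
    best linear unbiased prediction (GBLUP) under two equivalent mixed-model
    formulations (conditional expectation and mixed-model equations), EM-type
    restricted maximum likelihood estimation of variance components with
    per-term and per-block heritabilities, and a simulator of phased haplotype
    populations, Mendelian pedigrees and phenotypes for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    GenomicRanges,
    rtracklayer,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
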