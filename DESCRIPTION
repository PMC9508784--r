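Package: bsascan
Title: Bulked Segregant Analysis Trait Mapping with Delta SNP-Index Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps a monogenic recessive trait from pooled sequencing of
    phenotype-selected bulks in an F2 cross (BSA-seq / QTL-seq). Computes
    per-site SNP-indices oriented against a heterozygous parent, applies the
    standard depth and index filters, slides windows of Delta(SNP-index)
    along the genome, derives depth-dependent confidence thresholds by
    simulating the null bulk composition and read sampling, and calls
    candidate regions. Also provides chi-square tests of Mendelian
    segregation ratios, recombinant-based fine mapping from marker-genotype
    matrices, diagnostic indel marker screening by co-segregation, and a
    seeded simulator of F2 crosses (Haldane recombination) with pooled
    read depths for validation and power studies.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
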