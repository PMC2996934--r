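Package: lightsnp
Title: SNP Discovery and Resource Statistics from Light-Coverage Sanger Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-nucleotide polymorphism (SNP) and short
    deletion/insertion polymorphism (DIP) discovery from light-coverage,
    multi-individual Sanger sequence aligned to a consensus assembly.
    Implements Neighborhood Quality Standard (NQS) base qualification with a
    coverage cap, non-redundant site merging with discoverer tracking,
    per-individual SNP rates, discoverer-category partitions, windowed SNP
    density and window-occupancy curves, spacing-based genotyping-panel
    design with backfill, and empirical validation-rate arithmetic. A
    synthetic population and fosmid paired-end read generator emulates an
    eight-cat resequencing survey (six outbred domestic breeds, one deeply
    sequenced inbred individual with a homozygous tract mosaic, one divergent
    wildcat) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
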