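Package: orgdecay
Title: Comparative Analysis of Organellar Genome Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the degradation of plant organellar genomes:
    pseudogene classification from explicit open-reading-frame disruption
    thresholds (frameshifting indels, premature stop codons, truncations),
    detection and quantification of plastid-derived mitochondrial insertions
    (MIPTs) and dispersed repeats, read-pair link-graph scaffolding with
    coverage-depth profiling, and construction of gene/intron presence-absence
    content matrices across taxa. A fully deterministic synthetic-data
    generator plants degradation features with a ground-truth manifest so
    every pipeline stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
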