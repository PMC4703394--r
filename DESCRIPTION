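Package: tnspore
Title: Transposon-Insertion Sequencing Analysis of Bacterial Sporulation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for Mariner (himar1) transposon-insertion
    sequencing (Tn-seq) screens of Bacillus subtilis sporulation. Tallies
    transposon-junction reads at TA dinucleotide sites, screens genes for
    insertion depletion after heat-kill selection with a Mann-Whitney U rank
    test and fold-change thresholds, scans the genome with a sliding 13-TA-site
    window for loci whose disruption accelerates sporulation, and computes
    co-culture competitive indices and sporulation efficiencies from colony
    counts. Includes a fully seeded synthetic-library simulator (saturating
    Mariner insertion pools, per-gene fitness factors applied through a
    selection bottleneck, MmeI-style junction reads) so every stage of the
    pipeline can be verified against designed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
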