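Package: rloopm5c
Title: Bisulfite-Based RNA m5C Site Calling and R-Loop Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying where TRDMT1 (DNMT2)
    deposits 5-methylcytosine (m5C) on RNA and how those sites relate to
    R-loops. Implements spike-in-calibrated m5C calling from per-cytosine
    bisulfite count tables (exact binomial test against the non-conversion
    rate with Benjamini-Hochberg correction), classification of sites as
    TRDMT1-dependent or -independent from wild-type versus knockout
    methylation fold changes, damage-induction flagging, derivation of
    RNaseH-sensitive DRIP-seq peak sets and overlap enrichment of site
    classes against an unmethylated-cytosine background (Fisher exact
    test), strand-faceted observed-vs-expected grids over windowed GC skew
    and GC fraction, and positional nucleotide-context profiling around
    sites. A fully specified synthetic-data generator (genome, transcripts,
    planted R-loop regions, planted methylation, bisulfite counts, DRIP
    peaks with RNaseH controls, and a truth table) makes every stage
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
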