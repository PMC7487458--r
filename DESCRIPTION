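Package: ipscnv
Title: Reprogramming-Associated Copy-Number Variant Hotspot Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls copy-number variant (CNV) segments from per-probe integer
    copy-number states of SNP-array samples, isolates iPSC-specific (de novo)
    CNVs by paired comparison against parental cells, merges events across
    samples into loci by reciprocal overlap, screens loci against a population
    control cohort, and classifies reprogramming-associated CNV hotspots with
    a likelihood-ratio (G) chi-square test under Bonferroni correction.
    Also detects polymorphic CNV regions that rearrange between paired
    parental and iPSC samples, computes CNV burden (paired t-test) and
    segment size distributions, and ships a synthetic-cohort generator with a
    planted-truth table so every pipeline stage is testable without array
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
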