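Package: srnascout
Title: Seed-Based Network Ranking, Promoter Scanning, and Pull-Down
    Enrichment for Small-RNA Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for identifying bacterial small
    regulatory RNAs and their targets from transcriptomic data. Builds a
    cell-cycle co-expression network from gene-by-timepoint expression
    tables (clipped Pearson correlations with cutoff-based edge
    reduction), prioritises genes by a PageRank-style seed-weighted
    iterative ranking with a closed-form stable solution and
    self-predictability parameter tuning, scans upstream regions for
    strict sigma-factor -35/-10 promoter elements with constrained
    spacing, and analyses aptamer pull-down RNA-seq by a sliding-window
    procedure: 25-bp genome windows, RPKM quantification, a
    high-variance replicate correction, negative-binomial enrichment
    testing, significance filtering, adjacent-window merging, strand
    assignment and gene annotation. Small quantification helpers
    (relative CFU, Miller units, blot and Western normalisations,
    label-free-quantification fold changes) and fully seeded synthetic
    data generators for every pipeline stage are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
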