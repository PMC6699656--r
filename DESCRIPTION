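Package: panoric
Title: Positional Pan-Genome Analysis Along the oriC-terC Replication Axis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how gene conservation, prophages and genomic
    islands are distributed along the replication axis of circular bacterial
    chromosomes. Parses Proteinortho-style orthology tables, classifies
    pan-genome families (core, soft-core, accessory, with paralog and
    connectivity filters), computes per-gene ortholog scores, locates the
    origin of replication from cumulative GC disparity, DnaA-box density,
    local GC content and parAB proximity, and runs the positional statistics:
    sliding-window regression of conservation against distance from oriC,
    slope-population quantile-quantile analysis, eight-segment enrichment
    (ANOVA and Tukey HSD), and chromosome-thirds prophage/genomic-island
    analysis. A synthetic-cohort simulator with planted signals makes every
    stage testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    sandwich,
    lmtest,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
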