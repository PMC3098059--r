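Package: peakannot
Title: Batch Annotation and Overlap Statistics for ChIP Enriched Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating enriched genomic regions (ChIP-seq,
    ChIP-chip or CAGE peaks) against user-supplied feature sets: nearest
    transcription start site with strand-aware signed distances, relative
    position classification, overlap detection with a maximum-gap rule,
    merged peaks across replicates with Venn cell counts and pairwise
    hypergeometric overlap significance, extraction of peak flanking
    sequences for motif discovery, and hypergeometric GO-term enrichment of
    peak-adjacent genes with Benjamini-Hochberg adjustment. Includes
    readers and writers for BED, GFF and TSV region lists, a deterministic
    synthetic-data generator (genomes, gene models, peak sets, GO maps)
    and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
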