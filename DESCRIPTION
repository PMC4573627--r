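Package: mirpromoter
Title: MicroRNA Promoter Identification from Histone-Mark ChIP-Seq Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transcription start sites (TSSs) of plant microRNA
    genes from multi-mark histone-modification ChIP-Seq data. Aligned reads
    are binned into fixed-width genomic bins and normalized to reads per
    million per bin (RPM); strand-oriented multi-mark profiles around
    protein-coding gene TSSs train a radial-basis-kernel support vector
    machine against random genomic positions; each miRNA locus is then
    scanned up to 10 kb upstream, candidate bins are scored, converted to
    empirical p-values against decoy positions, and called under
    Benjamini-Hochberg FDR control. Calls are categorized as independent,
    shared with the upstream gene promoter, or not predicted, with intronic
    miRNAs flagged. Includes a seeded synthetic-genome simulator with
    planted promoter structure for end-to-end validation, metagene profile
    summaries, and cross-method TSS agreement counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
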