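Package: dodderlign
Title: Quantifying Lignin-Based Dodder Resistance in Tomato
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying lignin-based resistance of
    tomato stems to dodder (Cuscuta campestris) parasitism. Quantifies
    phloroglucinol-stained cortex lignin in stem cross-section images with an
    adaptive CIELAB histogram-peak threshold; selects differentially
    expressed genes from RNA-seq counts under a condition-by-genotype
    interaction model and a two-factor ANOVA with Benjamini-Hochberg false
    discovery control; clusters expression profiles with a t-SNE embedding
    and a density-based grouping that keeps an explicit noise group; builds
    per-cultivar gene co-expression networks with a normal-quantile edge
    threshold, community detection and hub ranking; filters
    resistance-specific SNPs by genotype set logic and scans promoter
    windows for the W-box (TTGACY) cis-element; and summarises lignin
    chemistry (acetyl-bromide soluble lignin, pyrogram monolignol
    composition). Ships synthetic-data generators that emulate stained stem
    sections, structured count matrices and cultivar variant tables so the
    whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods,
    png,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    vcfR,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
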