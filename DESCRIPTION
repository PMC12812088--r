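Package: jumpsieve
Title: Blank-Informed Tag-Jump Filtering and Diversity Analysis for
    Metabarcoding Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decontamination of metabarcoding ASV-by-sample count tables
    using thresholds derived from blank index combinations (unused
    tag pairs): a sequencing-error read-count filter and a conditional
    tag-jump filter based on per-observation read proportions and their
    divergence from an equal-share expectation. Downstream analysis
    includes complete-linkage OTU clustering at a fixed barcoding gap,
    tree collapsing to OTU representatives, OTU richness and Faith's
    phylogenetic diversity with sequencing-depth residual correction,
    Baselga partitioning of Sorensen beta diversity into turnover and
    nestedness (pairwise and multi-site, with group resampling), and
    exclusive-OTU overlap counts. A synthetic index-hopping simulator
    with per-observation ground truth supports benchmarking of any
    filtering rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
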