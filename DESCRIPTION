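Package: fucolink
Title: Fucoidan-Degrader Prediction and 16S-MAG Linking for Gut
    Microbiome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream inference for diet-intervention gut-microbiome
    studies built around metagenome-assembled genomes (MAGs). Scores
    genomes for fucoidan-degrading potential by the minimum Jensen-Shannon
    divergence of their functional gene-class distribution against a
    reference panel of known seaweed-polysaccharide degraders, links 16S
    rRNA representative sequences to MAGs by local-alignment hits filtered
    on alignment length and percent identity, computes community
    statistics (Chao1 and ACE richness, principal-component ordination,
    per-feature one-way ANOVA with Tukey HSD across diet groups), and
    correlates MAG abundance with host bodyweight by Spearman rank
    correlation with exact small-sample p-values. A synthetic-data module
    generates every pipeline input with known ground truth so the whole
    chain is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
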