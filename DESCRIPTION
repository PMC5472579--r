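Package: tregmir
Title: miRNA/mRNA Integration Analysis for TGF-beta/atRA-Induced Regulatory T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a microRNA/mRNA integration
    analysis for in vitro induced regulatory T cells (iTregs). One-colour
    microarray signal matrices for three culture conditions (freshly isolated
    naive T cells, activation with IL-2 alone, and activation with IL-2 plus
    TGF-beta and all-trans retinoic acid) are quantile normalized, replicate
    probes are averaged, and differential expression is assessed with an
    empirical-Bayes moderated t-test and Benjamini-Hochberg adjustment.
    Detection-call set logic identifies microRNAs detected exclusively under
    TGF-beta/atRA, TargetScan-style context++ predictions quantify how heavily
    the concordantly downregulated transcripts are targeted, and a local
    Fisher/EASE enrichment test scores pathway gene sets. A seeded synthetic
    data generator with planted ground truth makes every stage testable
    without any array download.
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
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
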