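Package: merscape
Title: Detection, Classification and Comparative Statistics of Bacterial
    Mercury-Resistance (mer) Operons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative genomics of mercury-resistant bacteria.
    Detects mer operons in annotated genomes by merA anchoring and gene
    neighborhood screening, classifies operon architecture, completeness and
    resistance spectrum, and annotates flanking mobile genetic elements and
    co-resident metal-resistance loci. Provides a lexicon-based census of
    antibiotic-resistance, metal-resistance and mobile-element genes with
    z-score and per-replicon views; permutation-based multivariate statistics
    (Bray-Curtis dissimilarity, PERMANOVA, homogeneity of multivariate
    dispersion, Kruskal-Wallis with Dunn post hoc tests, dual
    Pearson/Spearman correlation reporting, PCA and PCoA); neighbor-joining
    phylogenies of concatenated Mer proteins with Jukes-Cantor protein
    distances and bootstrap supports; prevalence-threshold classification of
    lifestyle-associated gene families; and a synthetic annotated-genome
    generator with machine-readable ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    rtracklayer,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    vegan,
    Biostrings,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
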