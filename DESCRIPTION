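Package: eukmag
Title: Screening, Trophic-Mode Scoring and Co-Occurrence Networks for
    Eukaryotic Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for the downstream computations of
    eukaryotic metagenome-assembled genome (MAG) recovery pipelines:
    length and domain-content screening of candidate bins, quality
    tiering from BUSCO/CheckM estimates, average-nucleotide-identity
    (ANI) dereplication with representative scoring, reconciliation of
    ab initio and protein-evidence exon structures into merged gene
    models, RPKM/CPM abundance normalisation, a KEGG-Ortholog-based
    trophic-mode classifier (hold-out permutation-importance feature
    selection plus a random forest) with a composite heterotrophy
    index, Spearman co-occurrence networks with Sidak edge filtering,
    Louvain communities and within/between-community connectedness,
    and phylogenetic diversity and gain on fixed trees. Synthetic
    fixture generators emulate the statistical structure of each input
    so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    ranger,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
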