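Package: phagepan
Title: Pan-Genome and Phylogenomic Analysis of Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics of small viral genomes: reciprocal-hit
    orthologous-group (COG) clustering from all-vs-all protein alignments,
    pan- and core-genome rarefaction curves, core/accessory/unique gene
    classification, concatenated core-gene and gene-content phylogenies with
    bootstrap support, tree-topology comparison via Robinson-Foulds distances
    and non-metric multidimensional scaling, compositional (G+C) group
    statistics, and a synthetic phage-genome simulator with planted
    orthology, cluster structure and ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    igraph,
    phangorn,
    vegan,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
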