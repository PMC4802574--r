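Package: rRNAregions
Title: Phylogenetic Sensitivity of 16S rRNA Hypervariable Regions via
    Tree-Space Geodesics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how faithfully each 16S rRNA hypervariable
    sub-region (V1-V9) reproduces the phylogeny obtained from the
    (near) full-length gene. Provides the sub-region coordinate system
    over SILVA-style alignments, length/taxonomy filtering, stratified
    per-phylum taxon sampling, distance-based neighbor-joining tree
    inference (with ingestion of externally built Newick trees), exact
    geodesic distances in Billera-Holmes-Vogtmann tree space computed
    with the GTP extension-problem algorithm (plus an exhaustive
    path-space oracle), majority-rule consensus of per-list
    agglomerative clusterings with node supports, a rank-based
    sensitivity classification of the regions, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Sequencing, Microbiome, Software
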