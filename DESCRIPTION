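Package: grouprank
Title: Disease-Gene Prioritization by Differentially Co-Expressed Gene
    Groups in a Protein-Protein Interaction Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate disease genes in a protein-protein interaction
    (PPI) network by their diffusion-kernel proximity to groups of
    coordinately differentially expressed genes. Differentially expressed
    genes are detected by Student t-tests with Bonferroni correction,
    partitioned into co-expressed groups by hierarchical clustering on a
    Pearson correlation distance, and each candidate gene is scored against
    every group by the geometric mean of its kernel similarities to the
    group members, weighted by the group's differential-expression level
    and damped by hub-degree and group-size penalties. Includes the
    single-gene baseline (SingleRank), rank-ratio and ROC/AUC evaluation,
    a distance-threshold sweep, a size-matched random-group permutation
    null, and a seeded synthetic benchmark generator with planted
    co-expressed modules adjacent to planted disease genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
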