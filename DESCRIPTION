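Package: ivignet
Title: Network-Based Mechanistic Analysis of IVIg Response Across Autoimmune Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-biology pipeline for relating the protein-target profile
    of pooled intravenous immunoglobulin (IVIg) to the molecular definition of
    autoimmune and inflammatory diseases grouped by clinical response cluster.
    Provides process-group frequency tables and chi-squared dependence tests
    per response cluster, protein-overlap similarity between clusters with an
    agglomerative binary similarity tree, Venn set algebra over cluster effector
    sets, hypergeometric pathway enrichment with Benjamini-Hochberg false
    discovery rate control, a Hausdorff-thresholded pathway similarity network,
    and a stratified bagged ensemble of small multilayer-perceptron classifiers
    that scores the topological relationship between a drug's target set and a
    disease's effector set over a protein-protein interaction network. Seeded
    synthetic-data generators (scale-free networks, disease panels, drug-indication
    training pairs, pathway databases) make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    igraph,
    nnet,
    ape,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
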