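Package: dignet
Title: Interactome Topology, Pathway Crosstalk and Steiner Subnetworks for
    Disease Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A systems-level toolkit for characterising a disease
    candidate-gene list against a protein-protein interaction network:
    topology statistics (degree, betweenness, shortest paths) with group
    comparisons, gene-set over-representation (hypergeometric and one-sided
    Fisher tests with Benjamini-Hochberg correction), pathway-crosstalk
    network construction from Jaccard and overlap coefficients with
    rule-based filtering and top-fraction edge retention, node-weighted
    Steiner-tree subnetwork extraction (Klein-Ravi spider merging) with a
    brute-force oracle, and GWAS-based validation via gene-wise minimum SNP
    p-values. Includes synthetic-data generators with planted ground truth
    for end-to-end testing, readers and writers for the standard formats
    (edge list, SIF, GMT, PLINK-style association tables, GraphML), and a
    staged pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
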