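Package: treetop
Title: Branch Point Detection in Single-Cell Data via Ensembles of
    Minimum Spanning Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and scores branch points, including multifurcations
    and multi-level hierarchies, in high-dimensional single-cell data
    (mass cytometry, flow cytometry, dimensionality-reduced scRNA-seq).
    A set of reference nodes is spread through the data by k-means++
    seeding, an ensemble of minimum spanning trees is sampled over one
    cell per Voronoi partition, and every node is scored for how
    consistently cutting the trees there splits the remaining nodes into
    three or more branches. Raw scores are normalized against reference
    score distributions computed from synthetic non-branching (triangular)
    data, yielding a relative branching score whose values above 1
    indicate evidence of branching. Includes a stochastic toggle-switch
    cascade simulator (tau-leaping with Hill-kinetics production) for
    generating hierarchically branching ground-truth data, preprocessing
    utilities (arcsinh transform, density-based downsampling, diffusion
    maps), force-directed layouts of the tree ensemble, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    data.table,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
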