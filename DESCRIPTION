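Package: agreetree
Title: Agreement Supertrees for Semi-Labeled Trees and Taxonomies
Version: 0.1.0
Authors@R:
    person("agreetree", "maintainers", email = "agreetree@example.org",
           role = c("aut", "cre"))
Description: Tests whether a collection of rooted semi-labeled trees
    (phylogenies whose internal nodes may carry taxon labels, such as
    taxonomies) admits an agreement supertree, and constructs one when it
    exists.  The agreement tree restricted to each input tree's taxon set is
    isomorphic to that input tree, so multifurcations are treated as hard
    facts.  The package provides Newick input/output for semi-labeled trees,
    a display-graph based top-down construction algorithm with decremental
    graph connectivity, an independent agreement verifier, a brute-force
    decider for small instances, a synthetic profile generator for
    benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ape
Config/testthat/edition: 3
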