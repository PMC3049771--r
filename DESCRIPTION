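Package: ppienrich
Title: Network Enrichment Analysis of Gene Modules on Protein-Protein
    Interaction Scaffolds
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps gene modules (functional categories, co-expression
    modules, expression signatures) onto a scaffold protein-protein
    interactome, builds the minimal connected network (MCN) each module
    induces -- optionally extended by single external linker nodes -- and
    tests four topological parameters (connection degree, clustering
    coefficient, relative betweenness centrality, number of connected
    components) against empirical null distributions obtained by
    repeatedly resampling equally sized random node sets. One-sided
    two-sample Kolmogorov-Smirnov tests are used for the node-level
    parameters and an empirical lower-tail test for component counts.
    Also provides batch summaries over module collections, pooled
    class-vs-class comparisons, term-DAG propagation with
    over-representation analysis, and synthetic benchmark generators
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
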