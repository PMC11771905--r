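Package: keyregnet
Title: Key Regulator Discovery in Gene Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A network-theoretic pipeline for identifying key regulator genes
    from two-group expression data: differential-expression screening with a
    moderated t-test and Benjamini-Hochberg correction, construction of a
    scored protein-protein interaction network, per-node topological profiling
    (degree distribution, clustering coefficient, neighbourhood connectivity,
    betweenness, closeness, eigenvector centrality), power-law fitting of the
    degree distribution by the Clauset maximum-likelihood procedure with a
    semi-parametric bootstrap goodness-of-fit test, recursive leading-eigenvector
    modularity bisection down to triangle (G(3,3)) motifs with dotted-path
    community labels, extraction of key regulators as the genes persisting to
    terminal motifs, and hypergeometric over-representation analysis against
    GMT gene-set collections. A synthetic-data module generates expression
    matrices with planted effects and benchmark graphs (preferential
    attachment, deterministic hierarchical, planted partition) so the whole
    chain is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
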