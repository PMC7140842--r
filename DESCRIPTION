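Package: netprops
Title: Topological Properties of Gene Sets in Protein Interaction Networks
Version: 1.0.0
Authors@R:
    person("netprops", "developers", email = "netprops@example.org",
           role = c("aut", "cre"))
Description: Analysis of how gene sets (for example cancer prognostic
    signatures) sit inside a protein-protein interaction network. Loads and
    cleans tab-separated edge lists and GMT gene sets, computes four node
    centralities (degree, betweenness, closeness, eigenvector) with one-tailed
    group comparisons, and provides set-level topological measures: set
    clustering coefficient, intra-set distance (mean shortest path within a
    set), inter-set distance (sum of the two directional mean cross-distances
    between sets), and genset-distribution-in-modules (fraction of a set's
    qualifying edges falling within detected network modules). Modules come
    from a deterministic multi-step greedy modularity maximizer with a
    minimum-size retention filter. Significance is assessed against random
    gene-set null distributions via one-tailed Kolmogorov-Smirnov and
    permutation tests, and module function via Fisher-test enrichment with
    term-size and evidence-code filters. Includes synthetic network and
    gene-set generators (planted partition, preferential attachment) so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
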