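Package: frontierNet
Title: Frontier-Based Graph Traversal and Analysis of Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Frontier-based graph traversal kernels for weighted biological
    networks: level-synchronous multi-source breadth-first search,
    Bellman-Ford single-source shortest paths with active-vertex frontiers
    (distances and predecessors), and a three-phase strongly-connected-
    component decomposition (trimming, forward-backward partitioning with a
    coverage-maximizing pivot heuristic, and coloring). Graphs are stored in
    compressed sparse row (CSR) form built from coordinate-list edge tables.
    On top of the kernels the package provides workflows for interaction-
    network analysis: score-threshold filtering of confidence-weighted edge
    lists, Pearson coexpression-network construction from expression
    matrices, component-based seed-gene subnetwork extraction, and mean
    shortest-path statistics, together with seeded synthetic generators
    (Erdos-Renyi graphs, score-weighted preferential-attachment networks,
    planted-component digraphs, modular expression matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
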