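# Independent reference implementations and fixture builders used across
# the suite. None of them share code paths with the package kernels: the
# BFS oracle is a plain FIFO queue over adjacency lists rebuilt from the
# edge table, the shortest-path oracle is the textbook |V|-1-sweep
# Bellman-Ford over the raw arc list, and igraph supplies a second,
# external opinion (Dijkstra distances, strong components).

# arc list (directed view) of a CSRGraph, rebuilt from the edge table
arcList <- function(g) {
  et <- asEdgeTable(g)
  from <- et$from; to <- et$to; w <- et$weight
  if (!isDirected(g)) {
    keep <- et$from != et$to
    from <- c(et$from, et$to[keep])
    to <- c(et$to, et$from[keep])
    w <- c(et$weight, et$weight[keep])
  }
  list(from = from, to = to, weight = w)
}

# classic FIFO-queue BFS depths from one source
queueBfsOracle <- function(g, s) {
  n <- numVertices(g)
  arcs <- arcList(g)
  adj <- vector("list", n)
  grp <- split(arcs$to, arcs$from)
  adj[as.integer(names(grp))] <- grp
  depth <- rep(Inf, n)
  depth[s] <- 0
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    for (v in adj[[u]]) {
      if (is.infinite(depth[v])) {
        depth[v] <- depth[u] + 1
        tail <- tail + 1L
        queue[tail] <- v
      }
    }
  }
  depth
}

# textbook Bellman-Ford: |V|-1 full sweeps over the arc list, then one
# detection sweep; returns NULL if a negative cycle is reachable
bellmanFordOracle <- function(g, s) {
  n <- numVertices(g)
  arcs <- arcList(g)
  dist <- rep(Inf, n)
  dist[s] <- 0
  for (i in seq_len(max(n - 1L, 0L))) {
    nd <- dist[arcs$from] + arcs$weight
    improved <- which(nd < dist[arcs$to])
    if (!length(improved)) break
    for (k in improved) {
      v <- arcs$to[k]
      cand <- dist[arcs$from[k]] + arcs$weight[k]
      if (cand < dist[v]) dist[v] <- cand
    }
  }
  nd <- dist[arcs$from] + arcs$weight
  if (any(nd < dist[arcs$to] & is.finite(nd))) return(NULL)
  dist
}

toIgraph <- function(g) {
  et <- asEdgeTable(g)
  igraph::graph_from_data_frame(
    data.frame(from = et$from, to = et$to, weight = et$weight),
    directed = isDirected(g),
    vertices = data.frame(name = seq_len(numVertices(g)))
  )
}

igraphDepths <- function(g, sources) {
  ig <- toIgraph(g)
  unname(igraph::distances(ig, v = sources, mode = "out", weights = NA))
}

igraphDijkstra <- function(g, sources) {
  ig <- toIgraph(g)
  unname(igraph::distances(ig, v = sources, mode = "out",
                           weights = igraph::E(ig)$weight,
                           algorithm = "dijkstra"))
}

igraphStrongMembership <- function(g) {
  ig <- toIgraph(g)
  unname(igraph::components(ig, mode = "strong")$membership)
}

# partition of 1..n as a canonical set of sorted member strings
partitionKey <- function(labels) {
  unname(sort(vapply(split(seq_along(labels), labels),
                     function(v) paste(v, collapse = ","), character(1))))
}

samePartition <- function(a, b) identical(partitionKey(a), partitionKey(b))

# is the component condensation acyclic?
condensationIsAcyclic <- function(g, labels) {
  et <- asEdgeTable(g)
  a <- labels[et$from]
  b <- labels[et$to]
  keep <- a != b
  if (!any(keep)) return(TRUE)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep]), directed = TRUE)
  igraph::is_dag(ig)
}

# seeded random CSR graph built from the package's own generator
randomGraph <- function(seed, n, p, directed = FALSE,
                        weightRange = c(1, 1)) {
  buildCSR(genErdosRenyi(n, p, directed = directed, seed = seed,
                         weightRange = weightRange),
           directed = directed)
}
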