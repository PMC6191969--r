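#' Filter a weighted edge table by a minimum score
#'
#' Keeps the records whose weight (e.g. a STRING-style combined confidence
#' score in 0..1000) is at least `minScore`. The vertex universe is
#' unchanged: vertices isolated by the filter remain in the graph, so
#' thresholds produce sparser networks over the same label set. Filtering
#' at `a` then at `b` equals filtering once at `max(a, b)`.
#'
#' @param edges an edge table ([edgeTable()]).
#' @param minScore numeric threshold; records with `weight >= minScore`
#'   are kept.
#' @return the filtered edge table (same `nVertices` and `labels`
#'   attributes).
#' @export
scoreFilter <- function(edges, minScore) {
  edges <- validateEdges(edges)
  keep <- edges$weight >= minScore
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nVertices") <- attr(edges, "nVertices")
  attr(out, "labels") <- attr(edges, "labels")
  out
}

#' Build a Pearson coexpression network from an expression matrix
#'
#' Computes the Pearson correlation r for every unordered pair of gene
#' rows and emits one undirected record per pair passing the threshold,
#' weighted by r itself. Under `mode = "absolute"` a pair passes when
#' `|r| >= threshold`; under `mode = "signed"` only positively correlated
#' pairs with `r >= threshold` pass. Genes with zero variance across
#' samples have undefined correlation and never take part in an edge;
#' genes with any missing value are likewise dropped (listwise deletion).
#' All genes — including the skipped ones — remain in the vertex universe,
#' so downstream graphs keep one vertex per input gene.
#'
#' @param expr numeric genes x samples matrix; row names are gene labels
#'   (defaults supplied when absent). At least 3 samples are required for
#'   a meaningful correlation.
#' @param threshold numeric in \[0, 1\].
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return an edge table over the input genes, weighted by r.
#' @examples
#' set.seed(1)
#' expr <- matrix(rnorm(40), nrow = 4,
#'                dimnames = list(paste0("g", 1:4), NULL))
#' expr[2, ] <- expr[1, ] * 2 + 1      # r = 1 with gene 1
#' correlationNetwork(expr, threshold = 0.9)
#' @export
correlationNetwork <- function(expr, threshold,
                               mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("insufficient samples: need at least 3")
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  nGenes <- nrow(expr)
  labels <- rownames(expr)
  if (is.null(labels)) labels <- paste0("gene", seq_len(nGenes))
  usable <- apply(expr, 1L, function(x) !anyNA(x) && stats::sd(x) > 0)
  idx <- which(usable)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  if (length(idx) >= 2L) {
    r <- stats::cor(t(expr[idx, , drop = FALSE]))
    pass <- if (mode == "absolute") abs(r) >= threshold else r >= threshold
    pass[lower.tri(pass, diag = TRUE)] <- FALSE
    sel <- which(pass, arr.ind = TRUE)
    sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
    from <- idx[sel[, 1L]]
    to <- idx[sel[, 2L]]
    w <- r[sel]
  }
  edgeTable(from, to, weight = w, nVertices = nGenes, labels = labels)
}

#' Map edge weights to traversal distances
#'
#' Raw edge weights are often similarities (correlation r, or an integer
#' confidence score) for which path length is meaningless; shortest-path
#' analysis needs a distance. `"one-minus-abs"` maps a correlation to
#' `1 - |r|`; `"max-minus-score"` maps a confidence score to
#' `maxScore - weight`; `"none"` passes weights through.
#'
#' @param edges an edge table.
#' @param transform one of `"none"`, `"one-minus-abs"`,
#'   `"max-minus-score"`.
#' @param maxScore ceiling for `"max-minus-score"` (default 1000, the
#'   STRING score scale).
#' @return the edge table with transformed weights.
#' @export
transformWeights <- function(edges,
                             transform = c("none", "one-minus-abs",
                                           "max-minus-score"),
                             maxScore = 1000) {
  transform <- match.arg(transform)
  edges <- validateEdges(edges)
  edges$weight <- switch(transform,
    none = edges$weight,
    `one-minus-abs` = 1 - abs(edges$weight),
    `max-minus-score` = maxScore - edges$weight
  )
  validateEdges(edges)
}

#' Extract the component subnetwork containing a seed vertex
#'
#' Finds the component of `seed` — the strongly connected component for a
#' directed graph, which on a symmetrically stored undirected graph is the
#' connected component — and returns the induced subgraph on it. This is
#' the seed-gene workflow: build a network, locate the seed's component,
#' and analyse paths within it.
#'
#' @param g a [CSRGraph-class]
#' @param seed integer vertex id (or a vertex label).
#' @param labels optional precomputed component labels from [scc()];
#'   computed on the fly when missing.
#' @return as [inducedSubgraph()]: a list with `graph` and `vertices`
#'   (old ids of the kept vertices).
#' @export
subnetworkWithSeed <- function(g, seed, labels = NULL) {
  stopifnot(is(g, "CSRGraph"))
  if (is.character(seed)) {
    seed <- match(seed, vertexLabels(g))
    if (is.na(seed)) stop("invalid vertex id: unknown seed label")
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 1L || seed > numVertices(g))
    stop("invalid vertex id")
  if (is.null(labels)) labels <- scc(g)
  inducedSubgraph(g, which(labels == labels[seed]))
}

#' Mean shortest-path distance from a set of sources
#'
#' Runs [sssp()] from every source and averages the finite source-to-target
#' distances over all ordered pairs with target != source. Unreachable
#' pairs are counted in `nPairsTotal` but excluded from the mean —
#' comparing the mean within a seed subnetwork against the mean over the
#' whole graph is the standard way to ask whether a module is more tightly
#' knit than its surroundings.
#'
#' @param g a [CSRGraph-class]
#' @param sources integer vertex ids (default: all vertices).
#' @return a list with `meanDistance` (mean over finite pairs; `NaN` when
#'   no pair is finite), `nPairsFinite` and `nPairsTotal`.
#' @export
meanShortestPath <- function(g, sources = seq_len(numVertices(g))) {
  stopifnot(is(g, "CSRGraph"))
  d <- distMatrix(sssp(g, sources, predecessors = FALSE))
  if (length(sources))
    d[cbind(seq_along(sources), as.integer(sources))] <- NA
  vals <- d[!is.na(d)]
  finite <- vals[is.finite(vals)]
  list(
    meanDistance = mean(finite),
    nPairsFinite = length(finite),
    nPairsTotal = length(vals)
  )
}
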