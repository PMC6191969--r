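#' Construct a validated edge table
#'
#' An edge table is the coordinate-list (COO) representation of a weighted
#' graph: a data frame with integer columns `from` and `to` (1-based,
#' contiguous vertex ids) and a numeric `weight` column, plus two
#' attributes: `nVertices` (the vertex universe, which may exceed the
#' largest id so isolated vertices survive filtering) and `labels`
#' (external vertex labels). Duplicate (from, to) pairs are permitted and
#' kept: they are parallel edges.
#'
#' @param from,to integer vertex ids in `1..nVertices`.
#' @param weight numeric edge weights, recycled to the record count;
#'   default 1.
#' @param nVertices vertex count; defaults to the largest id present
#'   (0 for an empty table).
#' @param labels character vertex labels, one per vertex; defaults to the
#'   decimal ids.
#' @return a validated edge table (see Details).
#' @examples
#' et <- edgeTable(c(1, 2), c(2, 3), weight = c(0.5, 2), nVertices = 4)
#' attr(et, "nVertices")
#' @export
edgeTable <- function(from, to, weight = 1, nVertices = NULL, labels = NULL) {
  if (length(from) != length(to))
    stop("'from' and 'to' must have equal length")
  from <- as.integer(from)
  to <- as.integer(to)
  weight <- rep_len(as.numeric(weight), length(from))
  if (is.null(nVertices))
    nVertices <- if (length(from)) max(from, to) else 0L
  nVertices <- as.integer(nVertices)
  if (is.null(labels)) labels <- as.character(seq_len(nVertices))
  et <- data.frame(from = from, to = to, weight = weight)
  attr(et, "nVertices") <- nVertices
  attr(et, "labels") <- as.character(labels)
  validateEdges(et)
}

#' Validate an edge table
#'
#' Checks that every endpoint id is an integer in `1..nVertices` and every
#' weight is finite (`NaN` and infinities are rejected). Returns the table
#' unchanged when valid.
#'
#' @param edges an edge table as built by [edgeTable()] (any data frame
#'   with `from`, `to`, `weight` columns and an `nVertices` attribute is
#'   accepted).
#' @param nVertices override for the vertex count attribute.
#' @return the validated edge table, invisibly unchanged.
#' @export
validateEdges <- function(edges, nVertices = attr(edges, "nVertices")) {
  if (!all(c("from", "to") %in% names(edges)))
    stop("edge table must have 'from' and 'to' columns")
  if (is.null(nVertices))
    nVertices <- if (nrow(edges)) max(edges$from, edges$to) else 0L
  n <- as.integer(nVertices)
  if (is.na(n) || n < 0L) stop("invalid vertex count")
  ids <- c(edges$from, edges$to)
  if (length(ids)) {
    if (anyNA(ids) || any(ids != floor(ids)) || min(ids) < 1L || max(ids) > n)
      stop("invalid vertex id: endpoints must be integers in 1..", n)
  }
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  if (any(!is.finite(w)))
    stop("invalid weight: weights must be finite")
  attr(edges, "nVertices") <- n
  if (is.null(attr(edges, "labels")))
    attr(edges, "labels") <- as.character(seq_len(n))
  edges
}

## Raw CSR constructor: arcs are taken verbatim (no mirroring), then
## canonicalized (sorted by tail, head, weight).
csrFromArcs <- function(from, to, weight, n, directed, labels) {
  o <- order(from, to, weight, method = "radix")
  new("CSRGraph",
    offsets = c(0L, cumsum(tabulate(from, nbins = n))),
    targets = as.integer(to[o]),
    weights = as.numeric(weight[o]),
    directed = directed,
    vertexLabels = as.character(labels)
  )
}

#' Build a CSR graph from an edge table
#'
#' Converts the coordinate-list edge table into the compressed sparse row
#' structure the traversal kernels operate on. For `directed = FALSE`
#' every record (u, v, w) with u != v is stored as the two arcs (u, v, w)
#' and (v, u, w); self-loops are stored once. Parallel edges are kept, not
#' collapsed: collapsing (e.g. to the minimum weight) would silently change
#' shortest-path semantics, while breadth-first search is insensitive to
#' them and Bellman-Ford simply relaxes all of them.
#'
#' @param edges an edge table ([edgeTable()] or [readEdgeCsv()] output).
#' @param directed logical; `FALSE` (the default, matching undirected
#'   protein-interaction networks) stores the symmetric closure.
#' @param nVertices,labels overrides for the edge-table attributes.
#' @return a [CSRGraph-class].
#' @examples
#' g <- buildCSR(edgeTable(c(1, 2, 1), c(2, 3, 3)), directed = TRUE)
#' numVertices(g)
#' numEdges(g)
#' @export
buildCSR <- function(edges, directed = FALSE,
                     nVertices = attr(edges, "nVertices"),
                     labels = attr(edges, "labels")) {
  edges <- validateEdges(edges, nVertices)
  n <- attr(edges, "nVertices")
  if (is.null(labels)) labels <- attr(edges, "labels")
  if (length(labels) != n)
    stop("labels must have one entry per vertex")
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  from <- edges$from
  to <- edges$to
  if (!directed) {
    keep <- from != to
    from2 <- c(from, to[keep])
    to2 <- c(to, from[keep])
    w2 <- c(w, w[keep])
    from <- from2; to <- to2; w <- w2
  }
  csrFromArcs(from, to, w, n, directed, labels)
}

#' Export a CSR graph back to an edge table
#'
#' Inverse of [buildCSR()]: for directed graphs every stored arc becomes a
#' record; for undirected graphs each mirror pair is collapsed back to one
#' record with `from <= to`. The result is canonically ordered, so
#' `asEdgeTable(buildCSR(et))` reproduces the canonicalized arc multiset of
#' `et` exactly.
#'
#' @param g a [CSRGraph-class]
#' @return an edge table (see [edgeTable()]).
#' @export
asEdgeTable <- function(g) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  from <- rep.int(seq_len(n), diff(g@offsets))
  to <- g@targets
  w <- g@weights
  if (!isDirected(g)) {
    keep <- from <= to
    from <- from[keep]; to <- to[keep]; w <- w[keep]
  }
  o <- order(from, to, w, method = "radix")
  et <- data.frame(from = from[o], to = to[o], weight = w[o])
  attr(et, "nVertices") <- n
  attr(et, "labels") <- vertexLabels(g)
  et
}

#' Transpose a graph
#'
#' Returns the graph with every arc reversed: (u, v, w) is an arc of the
#' result iff (v, u, w) is an arc of `g`. Transposing twice gives back the
#' canonical form of `g`; an undirected (symmetric) graph is unchanged.
#' The transpose drives backward reachability in the strongly-connected-
#' component decomposition.
#'
#' @param g a [CSRGraph-class]
#' @return the transposed [CSRGraph-class]
#' @export
transposeGraph <- function(g) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  from <- rep.int(seq_len(n), diff(g@offsets))
  csrFromArcs(g@targets, from, g@weights, n, g@directed, g@vertexLabels)
}

#' Extract the subgraph induced by a vertex set
#'
#' Keeps exactly the arcs whose two endpoints both belong to `vertices`,
#' relabelling the kept vertices to contiguous ids `1..length(vertices)`
#' in ascending order of their old ids.
#'
#' @param g a [CSRGraph-class]
#' @param vertices integer vertex ids to keep (duplicates ignored).
#' @return a list with components `graph` (the induced [CSRGraph-class])
#'   and `vertices` (integer vector: `vertices[i]` is the old id of new
#'   vertex `i`, i.e. the new-to-old mapping; `match(old, vertices)` gives
#'   old-to-new).
#' @export
inducedSubgraph <- function(g, vertices) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  vertices <- as.integer(vertices)
  if (anyNA(vertices) || length(vertices) &&
      (min(vertices) < 1L || max(vertices) > n))
    stop("invalid vertex id")
  keepIds <- sort(unique(vertices))
  newId <- integer(n)
  newId[keepIds] <- seq_along(keepIds)
  from <- rep.int(seq_len(n), diff(g@offsets))
  to <- g@targets
  sel <- newId[from] > 0L & newId[to] > 0L
  sub <- csrFromArcs(newId[from[sel]], newId[to[sel]], g@weights[sel],
                     length(keepIds), g@directed, vertexLabels(g)[keepIds])
  list(graph = sub, vertices = keepIds)
}

## Heads of all arcs leaving the given (duplicate-free) vertex set,
## in arc-slice order; optionally with the owning tail repeated per arc.
outNeighbors <- function(g, vs, withOwner = FALSE) {
  off <- g@offsets
  deg <- off[vs + 1L] - off[vs]
  total <- sum(deg)
  if (total == 0L) {
    if (withOwner) return(list(to = integer(0), owner = integer(0),
                               arc = integer(0)))
    return(integer(0))
  }
  idx <- sequence(deg, from = off[vs] + 1L)
  if (withOwner)
    list(to = g@targets[idx], owner = rep.int(seq_along(vs), deg), arc = idx)
  else g@targets[idx]
}

#' @rdname numVertices
#' @export
setMethod("numVertices", "CSRGraph",
          function(x) length(x@offsets) - 1L)

#' @rdname numEdges
#' @export
setMethod("numEdges", "CSRGraph", function(x) length(x@targets))

#' @rdname isDirected
#' @export
setMethod("isDirected", "CSRGraph", function(x) x@directed)

#' @rdname vertexLabels
#' @export
setMethod("vertexLabels", "CSRGraph", function(x) x@vertexLabels)

#' @rdname outDegree
#' @export
setMethod("outDegree", "CSRGraph", function(x) diff(x@offsets))

#' @rdname inDegree
#' @export
setMethod("inDegree", "CSRGraph",
          function(x) tabulate(x@targets, nbins = numVertices(x)))

setMethod("show", "CSRGraph", function(object) {
  cat(sprintf("CSRGraph: %d vertices, %d stored arcs (%s)\n",
              numVertices(object), numEdges(object),
              if (object@directed) "directed" else "undirected"))
  if (numEdges(object)) {
    w <- object@weights
    cat(sprintf("  weights in [%g, %g]\n", min(w), max(w)))
  }
})

#' @rdname distMatrix
#' @export
setMethod("distMatrix", "TraversalResult", function(x) x@dist)

#' @rdname predMatrix
#' @export
setMethod("predMatrix", "TraversalResult",
          function(x) if (length(x@pred)) x@pred else NULL)

#' @rdname sourceVertices
#' @export
setMethod("sourceVertices", "TraversalResult", function(x) x@sources)

setMethod("show", "TraversalResult", function(object) {
  nv <- ncol(object@dist)
  cat(sprintf("TraversalResult (%s): %d source(s) x %d vertices\n",
              object@kind, length(object@sources), nv))
  reached <- sum(is.finite(object@dist))
  cat(sprintf("  %d of %d (source, vertex) pairs reached\n",
              reached, length(object@dist)))
  if (length(object@pred)) cat("  predecessors recorded\n")
})
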