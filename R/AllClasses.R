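#' @import methods
NULL

#' CSRGraph: a graph in compressed sparse row form
#'
#' A directed or undirected graph stored as a compressed sparse row (CSR)
#' adjacency structure: `offsets` holds, for each vertex, the 0-based start
#' of its arc slice in `targets`/`weights`; vertex `v`'s out-arcs occupy
#' positions `offsets[v]+1 .. offsets[v+1]` of those arrays (1-based R
#' indexing into the arrays, contiguous 1-based vertex ids). Undirected
#' graphs are stored symmetrically: every input record (u, v, w) with
#' u != v contributes the two arcs (u, v, w) and (v, u, w); self-loops are
#' stored once. Within each vertex's slice, targets are sorted ascending
#' with ties on parallel arcs broken by ascending weight, so two graphs
#' with the same arc multiset compare identical slot-by-slot.
#'
#' @slot offsets integer vector of length `numVertices + 1`; non-decreasing,
#'   starts at 0, ends at the arc count.
#' @slot targets integer vector of arc heads, one per stored arc.
#' @slot weights numeric vector of arc weights, parallel to `targets`;
#'   all finite.
#' @slot directed logical scalar; `FALSE` means the arc set is the
#'   symmetric closure of the input records.
#' @slot vertexLabels character vector of external vertex labels, one per
#'   vertex (defaults to the decimal ids).
#'
#' @seealso [buildCSR()], [transposeGraph()], [inducedSubgraph()],
#'   [asEdgeTable()]
#' @export
setClass("CSRGraph",
  representation(
    offsets = "integer",
    targets = "integer",
    weights = "numeric",
    directed = "logical",
    vertexLabels = "character"
  )
)

setValidity("CSRGraph", function(object) {
  n <- length(object@offsets) - 1L
  m <- length(object@targets)
  msgs <- character(0)
  if (n < 0L) msgs <- c(msgs, "offsets must have length >= 1")
  if (length(object@directed) != 1L || is.na(object@directed))
    msgs <- c(msgs, "directed must be a single TRUE/FALSE")
  if (length(object@weights) != m)
    msgs <- c(msgs, "weights and targets must have equal length")
  if (length(object@vertexLabels) != n)
    msgs <- c(msgs, "vertexLabels must have one entry per vertex")
  if (n >= 0L) {
    if (object@offsets[1L] != 0L)
      msgs <- c(msgs, "offsets must start at 0")
    if (object@offsets[n + 1L] != m)
      msgs <- c(msgs, "offsets must end at the arc count")
    if (n > 0L && any(diff(object@offsets) < 0L))
      msgs <- c(msgs, "offsets must be non-decreasing")
  }
  if (m > 0L) {
    if (anyNA(object@targets) || min(object@targets) < 1L ||
        max(object@targets) > n)
      msgs <- c(msgs, "invalid vertex id in targets")
    if (any(!is.finite(object@weights)))
      msgs <- c(msgs, "invalid weight: all arc weights must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' TraversalResult: multi-source traversal output
#'
#' Holds the result of running a traversal kernel from `s` source vertices:
#' an `s x |V|` distance matrix (BFS depths in hops, or weighted
#' shortest-path distances), and for shortest-path runs optionally an
#' `s x |V|` predecessor matrix. Unreachable vertices carry `Inf` in the
#' distance matrix; the predecessor of a source, or of an unreached vertex,
#' is `NA`.
#'
#' @slot dist numeric matrix, one row per source; `dist[i, v]` is the
#'   distance from `sources[i]` to vertex `v`, `Inf` if unreachable.
#' @slot pred integer matrix of predecessor vertex ids (same shape as
#'   `dist`), or a 0x0 matrix when predecessors were not requested.
#' @slot sources integer vector of source vertex ids, one per row.
#' @slot kind `"bfs"` or `"sssp"`.
#'
#' @seealso [bfsMulti()], [sssp()]
#' @export
setClass("TraversalResult",
  representation(
    dist = "matrix",
    pred = "matrix",
    sources = "integer",
    kind = "character"
  )
)

setValidity("TraversalResult", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("bfs", "sssp"))
    msgs <- c(msgs, "kind must be 'bfs' or 'sssp'")
  if (nrow(object@dist) != length(object@sources))
    msgs <- c(msgs, "dist must have one row per source")
  if (length(object@pred) && !identical(dim(object@pred), dim(object@dist)))
    msgs <- c(msgs, "pred, when present, must match dist's shape")
  if (length(msgs)) msgs else TRUE
})
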