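#' One Bellman-Ford frontier relaxation pass
#'
#' Relaxes every out-arc of every vertex in the active frontier. Frontier
#' vertices are processed in ascending id order with live distance reads
#' (Gauss-Seidel style): an improvement made early in the pass is visible
#' to later relaxations within the same pass. This converges to the same
#' fixed point as relaxing against a frozen snapshot, in no more passes;
#' the fixed point, not the pass count, is the contract. Parallel arcs from
#' one tail to the same head are reduced to their minimum candidate before
#' updating. The returned frontier contains all and only the vertices whose
#' tentative distance was modified during the pass, deduplicated and in
#' ascending order.
#'
#' Ties between equal-cost predecessors resolve to the last strict
#' improvement in the canonical sweep order (ascending tail id, ascending
#' adjacency) — implementation-defined but deterministic.
#'
#' @param g a [CSRGraph-class]
#' @param frontier integer vector of active vertices, duplicate-free, each
#'   with a finite tentative distance.
#' @param dist numeric vector of tentative distances (`Inf` = unreached).
#' @param pred integer vector of tentative predecessors (`NA` = none).
#' @return a list with `frontier` (vertices improved this pass), `dist`
#'   and `pred` (both updated).
#' @seealso [sssp()] runs the pass loop to the fixed point.
#' @export
relaxFrontier <- function(g, frontier, dist, pred) {
  off <- g@offsets
  changed <- logical(length(dist))
  for (u in frontier) {
    lo <- off[u] + 1L
    hi <- off[u + 1L]
    if (lo > hi) next
    vs <- g@targets[lo:hi]
    nd <- dist[u] + g@weights[lo:hi]
    if (hi - lo > 0L && anyDuplicated(vs)) {
      o <- order(vs, nd, method = "radix")
      keep <- !duplicated(vs[o])
      vs <- vs[o][keep]
      nd <- nd[o][keep]
    }
    imp <- nd < dist[vs]
    if (any(imp)) {
      vi <- vs[imp]
      dist[vi] <- nd[imp]
      pred[vi] <- u
      changed[vi] <- TRUE
    }
  }
  list(frontier = which(changed), dist = dist, pred = pred)
}

#' Single-source shortest paths (frontier-based Bellman-Ford)
#'
#' Computes, for each source, the minimum total arc weight over all paths
#' to every vertex, by iterating [relaxFrontier()] until the frontier of
#' improved vertices comes up empty. Negative arc weights are accepted;
#' with no negative cycle reachable from a source the fixed point is
#' reached within `|V| - 1` passes, so a frontier still alive after `|V|`
#' full passes proves a reachable negative cycle and raises an error (the
#' only semantics under which "shortest path" is well defined).
#'
#' @param g a [CSRGraph-class] with finite weights.
#' @param sources integer vector of source vertex ids.
#' @param predecessors logical; record the shortest-path tree? When
#'   `TRUE` the result carries a predecessor matrix from which any
#'   shortest path can be reconstructed by walking back to the source.
#' @return a [TraversalResult-class] of kind `"sssp"`: distances are
#'   `Inf` for unreachable vertices; predecessors are `NA` for each source
#'   itself and for unreached vertices.
#' @examples
#' g <- buildCSR(edgeTable(c(1, 1, 3), c(2, 3, 2), weight = c(5, 1, 2)),
#'               directed = TRUE)
#' res <- sssp(g, 1)
#' distMatrix(res)   # vertex 2 is cheaper via 3: 1 + 2 = 3
#' predMatrix(res)
#' @export
sssp <- function(g, sources, predecessors = TRUE) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  sources <- as.integer(sources)
  if (anyNA(sources) || length(sources) &&
      (min(sources) < 1L || max(sources) > n))
    stop("invalid vertex id in sources")
  labs <- vertexLabels(g)
  dmat <- matrix(Inf, length(sources), n,
                 dimnames = list(labs[sources], labs))
  pmat <- if (predecessors)
    matrix(NA_integer_, length(sources), n,
           dimnames = list(labs[sources], labs))
  else matrix(NA_integer_, 0L, 0L)
  for (i in seq_along(sources)) {
    s <- sources[i]
    dist <- rep(Inf, n)
    pred <- rep(NA_integer_, n)
    dist[s] <- 0
    f <- s
    pass <- 0L
    while (length(f)) {
      pass <- pass + 1L
      if (pass > n)
        stop("negative cycle reachable from source ", labs[s])
      st <- relaxFrontier(g, f, dist, pred)
      f <- st$frontier
      dist <- st$dist
      pred <- st$pred
    }
    pred[s] <- NA_integer_
    dmat[i, ] <- dist
    if (predecessors) pmat[i, ] <- pred
  }
  new("TraversalResult", dist = dmat, pred = pmat,
      sources = sources, kind = "sssp")
}

#' Reconstruct one shortest path from a traversal result
#'
#' Walks the predecessor chain of `target` back to the source of result
#' row `row` and returns the path in source-to-target order. Errors if the
#' result has no predecessor matrix or the target was not reached.
#'
#' @param res a [TraversalResult-class] from [sssp()] with
#'   `predecessors = TRUE`.
#' @param target integer vertex id.
#' @param row which source row to use (default 1).
#' @return integer vector of vertex ids from the source to `target`.
#' @export
reconstructPath <- function(res, target, row = 1L) {
  pred <- predMatrix(res)
  if (is.null(pred)) stop("result carries no predecessors")
  d <- distMatrix(res)
  if (!is.finite(d[row, target])) stop("target not reached from source")
  s <- sourceVertices(res)[row]
  path <- target
  v <- target
  steps <- 0L
  while (v != s) {
    v <- pred[row, v]
    if (is.na(v) || (steps <- steps + 1L) > ncol(d))
      stop("broken predecessor chain")
    path <- c(v, path)
  }
  path
}
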