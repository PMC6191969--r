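#' One level-synchronous BFS propagation step
#'
#' Expands the current frontier by one level: every unvisited out-neighbor
#' of a frontier vertex is assigned depth `level + 1`, marked visited, and
#' placed in the next frontier. When several frontier vertices reach the
#' same unvisited neighbor in the same step they would each emit it; the
#' duplicates are filtered so the returned frontier contains each vertex
#' exactly once, in ascending id order (the canonical frontier order —
#' emission order is meaningless for a level-synchronous sweep).
#'
#' @param g a [CSRGraph-class]
#' @param frontier integer vector of the current level's vertices,
#'   duplicate-free; all must already be visited at depth `level`.
#' @param visited logical vector, one flag per vertex.
#' @param depths numeric vector of assigned depths (`Inf` = not yet
#'   reached).
#' @param level integer depth of the vertices in `frontier`.
#' @return a list with `frontier` (the deduplicated next frontier),
#'   `visited` and `depths` (both updated).
#' @seealso [bfsMulti()] runs the full loop over many sources.
#' @export
bfsStep <- function(g, frontier, visited, depths, level) {
  nb <- outNeighbors(g, frontier)
  nb <- nb[!visited[nb]]
  f2 <- sort.int(unique(nb), method = "radix")
  visited[f2] <- TRUE
  depths[f2] <- level + 1
  list(frontier = f2, visited = visited, depths = depths)
}

#' Multi-source breadth-first search
#'
#' Runs a level-synchronous, frontier-based BFS independently from each
#' source and collects the depths into one matrix with a row per source:
#' entry (i, v) is the minimum number of arcs on any path from
#' `sources[i]` to `v`, or `Inf` when `v` is unreachable. Arc weights are
#' ignored (depth is hop count). The loop terminates as soon as a frontier
#' comes up empty — after at most `|V|` steps, since the visited set grows
#' at every step.
#'
#' @param g a [CSRGraph-class]
#' @param sources integer vector of source vertex ids; duplicates are
#'   allowed and produce identical rows.
#' @return a [TraversalResult-class] of kind `"bfs"`. Row names are the
#'   source labels, column names the vertex labels.
#' @examples
#' g <- buildCSR(edgeTable(c(1, 2), c(2, 3)), directed = TRUE)
#' distMatrix(bfsMulti(g, 1))
#' @export
bfsMulti <- function(g, sources) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  sources <- as.integer(sources)
  if (anyNA(sources) || length(sources) &&
      (min(sources) < 1L || max(sources) > n))
    stop("invalid vertex id in sources")
  depths <- matrix(Inf, nrow = length(sources), ncol = n,
                   dimnames = list(vertexLabels(g)[sources],
                                   vertexLabels(g)))
  for (i in seq_along(sources)) {
    s <- sources[i]
    visited <- logical(n)
    d <- rep(Inf, n)
    visited[s] <- TRUE
    d[s] <- 0
    f <- s
    level <- 0L
    while (length(f)) {
      st <- bfsStep(g, f, visited, d, level)
      f <- st$frontier
      visited <- st$visited
      d <- st$depths
      level <- level + 1L
    }
    depths[i, ] <- d
  }
  new("TraversalResult", dist = depths,
      pred = matrix(NA_integer_, 0L, 0L),
      sources = sources, kind = "bfs")
}
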