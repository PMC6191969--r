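## Per-vertex count of arcs from `vs` into the active set, excluding
## self-loops: a self-loop never makes its vertex non-trivial on its own,
## so it counts as neither an active successor nor an active predecessor.
activeDegree <- function(g, vs, active) {
  ow <- outNeighbors(g, vs, withOwner = TRUE)
  if (!length(ow$to)) return(integer(length(vs)))
  ok <- active[ow$to] & ow$to != vs[ow$owner]
  tabulate(ow$owner[ok], nbins = length(vs))
}

## Reachability closure from `start` along g's arcs, restricted to the
## membership vector `memb` (logical, length |V|). Returns a logical map.
reachWithin <- function(g, start, memb) {
  seen <- logical(length(memb))
  seen[start] <- TRUE
  f <- start
  while (length(f)) {
    nb <- outNeighbors(g, f)
    nb <- nb[memb[nb] & !seen[nb]]
    f <- unique(nb)
    seen[f] <- TRUE
  }
  seen
}

#' Trim trivial strongly connected components
#'
#' Phase 1 of the decomposition: repeatedly removes active vertices with no
#' active successor or no active predecessor — such a vertex cannot lie on
#' any cycle within the active set, so it is a trivial (singleton)
#' component. Removal cascades (a vertex may lose its last active neighbor
#' when another is trimmed), so the procedure iterates to a fixed point;
#' on a DAG it resolves the whole graph by itself. A self-loop counts as
#' neither an active successor nor predecessor: a vertex whose only cycle
#' is its self-loop is still a trivial component.
#'
#' @param g a directed [CSRGraph-class]
#' @param gT its transpose ([transposeGraph()]).
#' @param active logical vector: `TRUE` = not yet assigned to a component.
#'   Pass a subset's membership map to trim within that subset only (sound
#'   whenever the subset is SCC-closed).
#' @param labels integer vector of component labels (`NA` = unassigned).
#' @return a list with `active` and `labels` (updated; each trimmed vertex
#'   labelled with its own id) and `trimmed` (the removal count).
#' @export
trimTrivial <- function(g, gT, active, labels) {
  trimmed <- 0L
  repeat {
    vs <- which(active)
    if (!length(vs)) break
    outd <- activeDegree(g, vs, active)
    ind <- activeDegree(gT, vs, active)
    drop <- vs[outd == 0L | ind == 0L]
    if (!length(drop)) break
    labels[drop] <- drop
    active[drop] <- FALSE
    trimmed <- trimmed + length(drop)
  }
  list(active = active, labels = labels, trimmed = trimmed)
}

#' Choose a forward-backward pivot
#'
#' Coverage-maximizing heuristic: among the subset's vertices, pick the one
#' with the largest product of within-subset out-degree and in-degree
#' (self-loops excluded), breaking ties by smallest id. A high-degree pivot
#' tends to have large forward and backward closures, so one
#' forward-backward round classifies more of the subset.
#'
#' @param g a directed [CSRGraph-class]
#' @param gT its transpose.
#' @param subset non-empty integer vector of vertex ids.
#' @return the pivot's vertex id.
#' @export
selectPivot <- function(g, gT, subset) {
  subset <- as.integer(subset)
  if (!length(subset)) stop("empty pivot set")
  memb <- logical(numVertices(g))
  memb[subset] <- TRUE
  score <- as.numeric(activeDegree(g, subset, memb)) *
    as.numeric(activeDegree(gT, subset, memb))
  o <- order(-score, subset, method = "radix")
  subset[o[1L]]
}

#' Forward-backward partition around a pivot
#'
#' Phase 2 of the decomposition. Computes the forward closure `FWD` and
#' backward closure `BWD` of the pivot, both restricted to `subset`, and
#' splits the subset into four parts: the pivot's strongly connected
#' component `FWD intersect BWD`; the forward-only and backward-only
#' residues; and the remainder reached by neither closure. The three
#' residues are each SCC-closed — no component straddles them — so they can
#' be decomposed independently.
#'
#' @param g a directed [CSRGraph-class]
#' @param gT its transpose.
#' @param subset integer vector of vertex ids (an SCC-closed set).
#' @param pivot a member of `subset`.
#' @return a list of sorted integer vectors `scc`, `fwdOnly`, `bwdOnly`,
#'   `remainder`, which partition `subset`.
#' @export
forwardBackward <- function(g, gT, subset, pivot) {
  subset <- as.integer(subset)
  if (!pivot %in% subset) stop("invalid pivot")
  memb <- logical(numVertices(g))
  memb[subset] <- TRUE
  fwd <- reachWithin(g, pivot, memb)
  bwd <- reachWithin(gT, pivot, memb)
  list(
    scc = subset[fwd[subset] & bwd[subset]],
    fwdOnly = subset[fwd[subset] & !bwd[subset]],
    bwdOnly = subset[!fwd[subset] & bwd[subset]],
    remainder = subset[!fwd[subset] & !bwd[subset]]
  )
}

#' Coloring decomposition of the residual graph
#'
#' Phase 3 of the decomposition, applied to whatever the earlier phases
#' left active. Each active vertex starts with a unique color (its own
#' id); the maximum color is propagated along arcs to active successors
#' until no update is possible. Vertices whose color is unchanged (still
#' their own id) become pivots: the backward closure of a pivot restricted
#' to its color class is exactly one strongly connected component. Those
#' components are removed and the procedure repeats until nothing is
#' active. At least one vertex (the largest active id) keeps its color
#' every round, so the loop always terminates.
#'
#' @param g a directed [CSRGraph-class]
#' @param gT its transpose.
#' @param active logical membership vector of the residual vertices.
#' @param labels integer component labels to fill in (`NA` = unassigned).
#' @return a list with `labels` (every formerly active vertex labelled by
#'   its component's smallest member) and `active` (all `FALSE`).
#' @export
coloringDecompose <- function(g, gT, active, labels) {
  n <- numVertices(g)
  while (any(active)) {
    act <- which(active)
    color <- integer(n)
    color[act] <- act
    ow <- outNeighbors(g, act, withOwner = TRUE)
    us <- act[ow$owner]
    vs <- ow$to
    keep <- active[vs]
    us <- us[keep]
    vs <- vs[keep]
    if (length(vs)) {
      grp <- split(us, vs)
      heads <- as.integer(names(grp))
      repeat {
        cand <- vapply(grp, function(tails) max(color[tails]), integer(1))
        upd <- cand > color[heads]
        if (!any(upd)) break
        color[heads[upd]] <- cand[upd]
      }
    }
    pivots <- act[color[act] == act]
    for (p in pivots) {
      classMemb <- logical(n)
      cls <- act[color[act] == p]
      classMemb[cls] <- TRUE
      comp <- which(reachWithin(gT, p, classMemb))
      labels[comp] <- min(comp)
      active[comp] <- FALSE
    }
  }
  list(labels = labels, active = active)
}

#' Strongly connected components (three-phase decomposition)
#'
#' Decomposes a directed graph into its strongly connected components by
#' the trim / forward-backward / coloring pipeline: (1) trimming removes
#' trivial components to a fixed point; (2) `fbRounds` rounds of
#' forward-backward partitioning peel off the pivot components of the
#' surviving SCC-closed subsets, each subset being trimmed first; (3) the
#' coloring decomposition resolves whatever remains. The answer — the true
#' component partition — is identical for every `fbRounds >= 0`; the
#' parameter only shifts work between phases 2 and 3.
#'
#' Component ids are canonical: each component is labelled with the
#' smallest vertex id it contains, making the output independent of phase
#' scheduling. On an undirected (symmetrically stored) graph the strongly
#' connected components are exactly the connected components.
#'
#' @param g a [CSRGraph-class]
#' @param fbRounds non-negative integer; forward-backward rounds before
#'   switching to coloring (default 1).
#' @return a named integer vector of component ids, one per vertex; names
#'   are the vertex labels.
#' @examples
#' g <- buildCSR(edgeTable(c(1, 2, 3, 3), c(2, 3, 1, 4)), directed = TRUE)
#' scc(g)   # the 3-cycle {1,2,3} plus the singleton {4}
#' @export
scc <- function(g, fbRounds = 1L) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  if (n == 0L) return(setNames(integer(0), character(0)))
  fbRounds <- as.integer(fbRounds)
  if (is.na(fbRounds) || fbRounds < 0L)
    stop("fbRounds must be a non-negative integer")
  gT <- transposeGraph(g)
  labels <- rep(NA_integer_, n)
  active <- rep(TRUE, n)
  tr <- trimTrivial(g, gT, active, labels)
  active <- tr$active
  labels <- tr$labels
  worklist <- if (any(active)) list(which(active)) else list()
  for (r in seq_len(fbRounds)) {
    if (!length(worklist)) break
    nxt <- list()
    for (subset in worklist) {
      memb <- logical(n)
      memb[subset] <- TRUE
      tr <- trimTrivial(g, gT, memb, labels)
      labels <- tr$labels
      sub <- which(tr$active)
      if (!length(sub)) next
      p <- selectPivot(g, gT, sub)
      fb <- forwardBackward(g, gT, sub, p)
      labels[fb$scc] <- min(fb$scc)
      for (part in fb[c("fwdOnly", "bwdOnly", "remainder")])
        if (length(part)) nxt[[length(nxt) + 1L]] <- part
    }
    worklist <- nxt
  }
  active <- logical(n)
  active[unlist(worklist)] <- TRUE
  labels <- coloringDecompose(g, gT, active, labels)$labels
  setNames(labels, vertexLabels(g))
}
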