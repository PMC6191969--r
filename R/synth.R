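## Evaluate `code` under a Mersenne-Twister stream seeded with `seed`,
## restoring the caller's .Random.seed afterwards: generators are pure
## functions of their arguments and never disturb global RNG state.
withSeed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  code
}

#' Generate an Erdős–Rényi random graph
#'
#' Each vertex pair — ordered for directed graphs, unordered for
#' undirected — is included independently with probability `p`. Weights
#' are drawn uniformly from `weightRange` (the default collapses to
#' constant 1). Identical arguments always produce an identical edge
#' table.
#'
#' @param n vertex count.
#' @param p inclusion probability in \[0, 1\].
#' @param directed logical.
#' @param seed integer RNG seed.
#' @param weightRange numeric `(low, high)`; weights are uniform in the
#'   range, constant when `low == high`.
#' @return an edge table.
#' @export
genErdosRenyi <- function(n, p, directed = FALSE, seed = 1L,
                          weightRange = c(1, 1)) {
  stopifnot(n >= 0, p >= 0, p <= 1)
  n <- as.integer(n)
  if (n < 2L) {
    from <- integer(0)
    to <- integer(0)
  } else if (directed) {
    from <- rep(seq_len(n), each = n - 1L)
    to <- unlist(lapply(seq_len(n), function(i) seq_len(n)[-i]),
                 use.names = FALSE)
  } else {
    from <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
    to <- unlist(lapply(seq_len(n - 1L), function(i) seq.int(i + 1L, n)),
                 use.names = FALSE)
  }
  withSeed(seed, {
    keep <- stats::runif(length(from)) < p
    from <- from[keep]
    to <- to[keep]
    w <- if (weightRange[1] == weightRange[2])
      rep(weightRange[1], length(from))
    else stats::runif(length(from), weightRange[1], weightRange[2])
    edgeTable(from, to, weight = w, nVertices = n)
  })
}

#' Generate a score-weighted preferential-attachment network
#'
#' Emulates a confidence-scored interaction network at desk scale: a
#' Barabási–Albert-style undirected topology (each new vertex attaches to
#' `m` existing vertices chosen with probability proportional to degree,
#' giving the heavy-tailed degree distribution typical of
#' protein-interaction networks) with independent integer scores uniform
#' in `weightRange` (default 1..999, mimicking combined-confidence
#' scores). With `m = 1` the result is a tree of exactly `n - 1` records.
#'
#' @param n vertex count (>= 2).
#' @param m arcs attached per new vertex (>= 1).
#' @param seed integer RNG seed.
#' @param weightRange integer `(low, high)` score range.
#' @return an undirected edge table with integer-valued weights.
#' @export
genStringLike <- function(n, m = 3L, seed = 1L, weightRange = c(1L, 999L)) {
  n <- as.integer(n)
  m <- as.integer(m)
  stopifnot(n >= 2L, m >= 1L)
  withSeed(seed, {
    from <- integer(0)
    to <- integer(0)
    ## endpoint pool: each vertex appears once per incident edge, so
    ## uniform sampling from the pool is degree-proportional attachment
    pool <- 1L
    for (v in seq.int(2L, n)) {
      k <- min(m, v - 1L)
      cand <- unique(pool[sample.int(length(pool), length(pool))])[seq_len(k)]
      from <- c(from, rep.int(v, k))
      to <- c(to, cand)
      pool <- c(pool, cand, rep.int(v, k))
    }
    w <- sample.int(weightRange[2] - weightRange[1] + 1L,
                    length(from), replace = TRUE) + weightRange[1] - 1L
    edgeTable(from, to, weight = as.numeric(w), nVertices = n)
  })
}

#' Generate a digraph with planted strongly connected components
#'
#' Ground-truth generator for component recovery: vertices are split into
#' consecutive blocks of the given sizes; each block of size >= 2 is wired
#' as a directed Hamiltonian cycle (guaranteeing mutual reachability) plus
#' random intra-block arcs; arcs between blocks run only from earlier to
#' later blocks, so the block condensation is acyclic by construction and
#' the blocks are exactly the strongly connected components.
#'
#' @param blockSizes integer vector of block sizes, each >= 1.
#' @param seed integer RNG seed.
#' @param pIntra probability of each extra intra-block arc.
#' @param pInter probability of each forward inter-block arc.
#' @return a list with `edges` (directed edge table, unit weights) and
#'   `membership` (integer vector: for each vertex, the id of its planted
#'   block's smallest member — directly comparable to [scc()] labels).
#' @export
genPlantedScc <- function(blockSizes, seed = 1L, pIntra = 0.15,
                          pInter = 0.05) {
  blockSizes <- as.integer(blockSizes)
  stopifnot(length(blockSizes) >= 1L, all(blockSizes >= 1L))
  n <- sum(blockSizes)
  ends <- cumsum(blockSizes)
  starts <- ends - blockSizes + 1L
  membership <- rep.int(starts, blockSizes)
  withSeed(seed, {
    from <- integer(0)
    to <- integer(0)
    for (b in seq_along(blockSizes)) {
      vs <- seq.int(starts[b], ends[b])
      if (length(vs) >= 2L) {
        from <- c(from, vs)
        to <- c(to, c(vs[-1L], vs[1L]))
        pf <- rep.int(vs, length(vs))
        pt <- rep(vs, each = length(vs))
        ok <- pf != pt & stats::runif(length(pf)) < pIntra
        from <- c(from, pf[ok])
        to <- c(to, pt[ok])
      }
      if (b < length(blockSizes)) {
        later <- seq.int(ends[b] + 1L, n)
        pf <- rep.int(vs, length(later))
        pt <- rep(later, each = length(vs))
        ok <- stats::runif(length(pf)) < pInter
        from <- c(from, pf[ok])
        to <- c(to, pt[ok])
      }
    }
    list(
      edges = edgeTable(from, to, weight = 1, nVertices = n),
      membership = membership
    )
  })
}

#' Generate a modular gene-expression matrix
#'
#' Emulates the coexpression-analysis input: genes assigned to the same
#' module share a latent per-sample factor, mixed with independent
#' Gaussian noise. A gene in module `k` is
#' `mixing * factor_k + sqrt(1 - mixing^2) * noise`, so the expected
#' within-module Pearson correlation is `mixing^2` and `mixing = 1` gives
#' exactly correlated (identical) module rows. Background genes
#' (assignment 0) are pure independent noise, uncorrelated in expectation
#' with everything.
#'
#' @param nSamples number of samples (columns), >= 3.
#' @param moduleAssignments integer vector, one entry per gene: module
#'   number, or 0 for background.
#' @param mixing numeric in \[0, 1\]: latent-factor loading shared by all
#'   module genes.
#' @param seed integer RNG seed.
#' @return a genes x samples numeric matrix with gene and sample labels.
#' @export
genExpression <- function(nSamples, moduleAssignments, mixing = 0.9,
                          seed = 1L) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 3L) stop("insufficient samples: need at least 3")
  stopifnot(mixing >= 0, mixing <= 1)
  moduleAssignments <- as.integer(moduleAssignments)
  nGenes <- length(moduleAssignments)
  withSeed(seed, {
    mods <- sort(unique(moduleAssignments[moduleAssignments > 0L]))
    factors <- matrix(stats::rnorm(length(mods) * nSamples),
                      nrow = length(mods))
    expr <- matrix(0, nGenes, nSamples)
    for (i in seq_len(nGenes)) {
      noise <- stats::rnorm(nSamples)
      m <- moduleAssignments[i]
      expr[i, ] <- if (m > 0L)
        mixing * factors[match(m, mods), ] + sqrt(1 - mixing^2) * noise
      else noise
    }
    dimnames(expr) <- list(
      sprintf("gene%03d", seq_len(nGenes)),
      sprintf("sample%03d", seq_len(nSamples))
    )
    expr
  })
}
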