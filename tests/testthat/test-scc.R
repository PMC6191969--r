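cycleGraph <- function(ids, n = max(ids)) {
  buildCSR(edgeTable(ids, c(ids[-1], ids[1]), nVertices = n),
           directed = TRUE)
}

test_that("trimming resolves DAGs and leaves cycles alone", {
  dag <- buildCSR(edgeTable(c(1, 2), c(2, 3)), directed = TRUE)
  tr <- trimTrivial(dag, transposeGraph(dag), rep(TRUE, 3),
                    rep(NA_integer_, 3))
  expect_identical(tr$trimmed, 3L)
  expect_false(any(tr$active))
  expect_identical(tr$labels, 1:3)

  cyc <- cycleGraph(1:3)
  tr <- trimTrivial(cyc, transposeGraph(cyc), rep(TRUE, 3),
                    rep(NA_integer_, 3))
  expect_identical(tr$trimmed, 0L)
  expect_true(all(tr$active))

  # cycle {1,2,3} plus pendant 4 hanging off 3: only the pendant goes
  pend <- buildCSR(edgeTable(c(1, 2, 3, 3), c(2, 3, 1, 4)),
                   directed = TRUE)
  tr <- trimTrivial(pend, transposeGraph(pend), rep(TRUE, 4),
                    rep(NA_integer_, 4))
  expect_identical(tr$trimmed, 1L)
  expect_identical(which(!tr$active), 4L)

  # a vertex whose only cycle is its self-loop is still trivial
  loop <- buildCSR(edgeTable(1, 1, nVertices = 1), directed = TRUE)
  tr <- trimTrivial(loop, transposeGraph(loop), TRUE, NA_integer_)
  expect_identical(tr$trimmed, 1L)
})

test_that("pivot choice maximizes the active degree product", {
  single <- buildCSR(edgeTable(integer(0), integer(0), nVertices = 6),
                     directed = TRUE)
  expect_identical(selectPivot(single, transposeGraph(single), 6L), 6L)
  expect_error(selectPivot(single, transposeGraph(single), integer(0)),
               "empty pivot set")

  # hub 3 with in-star from {1,2} and out-star to {4,5}
  hub <- buildCSR(edgeTable(c(1, 2, 3, 3), c(3, 3, 4, 5)),
                  directed = TRUE)
  expect_identical(selectPivot(hub, transposeGraph(hub), 1:5), 3L)

  # a simple cycle: all degree products equal, smallest id wins
  cyc <- cycleGraph(1:4)
  expect_identical(selectPivot(cyc, transposeGraph(cyc), 1:4), 1L)
})

test_that("forward-backward partitions a subset into four closed parts", {
  cyc <- cycleGraph(1:3)
  fb <- forwardBackward(cyc, transposeGraph(cyc), 1:3, 1L)
  expect_identical(fb$scc, 1:3)
  expect_identical(fb$fwdOnly, integer(0))
  expect_identical(fb$bwdOnly, integer(0))
  expect_identical(fb$remainder, integer(0))

  path <- buildCSR(edgeTable(c(1, 2), c(2, 3)), directed = TRUE)
  fb <- forwardBackward(path, transposeGraph(path), 1:3, 2L)
  expect_identical(fb$scc, 2L)
  expect_identical(fb$fwdOnly, 3L)
  expect_identical(fb$bwdOnly, 1L)
  expect_identical(fb$remainder, integer(0))
  expect_error(forwardBackward(path, transposeGraph(path), 1:2, 3L),
               "invalid pivot")

  # two 3-cycles A = {1,2,3}, B = {4,5,6}, one bridge A -> B
  two <- buildCSR(edgeTable(c(1, 2, 3, 4, 5, 6, 1),
                            c(2, 3, 1, 5, 6, 4, 4)), directed = TRUE)
  fb <- forwardBackward(two, transposeGraph(two), 1:6, 1L)
  expect_identical(fb$scc, 1:3)
  expect_identical(fb$fwdOnly, 4:6)
  expect_identical(fb$remainder, integer(0))

  # the four parts always partition the subset
  g <- randomGraph(21, 40, 0.06, directed = TRUE)
  fb <- forwardBackward(g, transposeGraph(g), 1:40,
                        selectPivot(g, transposeGraph(g), 1:40))
  parts <- c(fb$scc, fb$fwdOnly, fb$bwdOnly, fb$remainder)
  expect_identical(sort(parts), 1:40)
})

test_that("coloring decomposes the residual graph", {
  # two disjoint 2-cycles: colors converge to {2,2,4,4}; pivots 2 and 4
  two <- buildCSR(edgeTable(c(1, 2, 3, 4), c(2, 1, 4, 3)),
                  directed = TRUE)
  res <- coloringDecompose(two, transposeGraph(two), rep(TRUE, 4),
                           rep(NA_integer_, 4))
  expect_identical(res$labels, c(1L, 1L, 3L, 3L))
  expect_false(any(res$active))

  single <- buildCSR(edgeTable(integer(0), integer(0), nVertices = 1),
                     directed = TRUE)
  res <- coloringDecompose(single, transposeGraph(single), TRUE,
                           NA_integer_)
  expect_identical(res$labels, 1L)

  # 3-cycle: all colors converge to 3, whose backward closure is the cycle
  cyc <- cycleGraph(1:3)
  res <- coloringDecompose(cyc, transposeGraph(cyc), rep(TRUE, 3),
                           rep(NA_integer_, 3))
  expect_identical(res$labels, c(1L, 1L, 1L))
})

test_that("the full pipeline recovers known component structures", {
  dag <- buildCSR(edgeTable(c(1, 1, 2, 3), c(2, 3, 4, 5)),
                  directed = TRUE)
  expect_identical(unname(scc(dag)), 1:5)

  mix <- buildCSR(edgeTable(c(1, 2, 3), c(2, 3, 1), nVertices = 4),
                  directed = TRUE)
  expect_identical(unname(scc(mix)), c(1L, 1L, 1L, 4L))

  pl <- genPlantedScc(c(5, 10, 20), seed = 7)
  g <- buildCSR(pl$edges, directed = TRUE)
  expect_identical(unname(scc(g)), pl$membership)
  expect_true(samePartition(scc(g), igraphStrongMembership(g)))

  # symmetric storage: strong components are the connected components
  und <- randomGraph(31, 60, 0.03, directed = FALSE)
  ig <- toIgraph(und)
  expect_true(samePartition(
    scc(und), igraph::components(ig, mode = "weak")$membership))
})

test_that("the partition is correct however work is split across phases", {
  set.seed(77)
  sizes <- sample(10:120, 30, replace = TRUE)
  dens <- sample(c(0.5, 1, 2, 4), 30, replace = TRUE)
  for (k in 1:30) {
    g <- randomGraph(k + 500, sizes[k], min(1, dens[k] / sizes[k]),
                     directed = TRUE)
    want <- igraphStrongMembership(g)
    for (fb in c(0L, 1L, 3L)) {
      got <- scc(g, fbRounds = fb)
      expect_true(samePartition(got, want))
      # canonical ids: each component labelled by its smallest member
      expect_true(all(vapply(split(seq_along(got), got),
                             function(v) min(v), integer(1)) ==
                      as.integer(names(split(seq_along(got), got)))))
    }
    expect_true(condensationIsAcyclic(g, scc(g)))
  }
})
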