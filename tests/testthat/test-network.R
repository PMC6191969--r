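test_that("score filtering keeps the vertex universe and composes", {
  et <- edgeTable(c(1, 2, 3), c(2, 3, 4), weight = c(100, 250, 950),
                  nVertices = 5)
  expect_identical(nrow(scoreFilter(et, 200)), 2L)
  expect_identical(attr(scoreFilter(et, 200), "nVertices"), 5L)
  expect_identical(scoreFilter(et, 0)$weight, et$weight)

  sl <- genStringLike(300, m = 2, seed = 19)
  f900 <- scoreFilter(sl, 900)
  expect_identical(nrow(f900), sum(sl$weight >= 900))

  # filter at a then b == filter at max(a, b)
  expect_identical(scoreFilter(scoreFilter(sl, 200), 700)$weight,
                   scoreFilter(sl, 700)$weight)
  expect_identical(scoreFilter(scoreFilter(sl, 700), 200)$weight,
                   scoreFilter(sl, 700)$weight)
})

test_that("correlation networks threshold Pearson r with sign control", {
  set.seed(101)
  base <- matrix(rnorm(30, sd = 1), nrow = 1)
  expr <- rbind(base, 2 * base + 3, -base)
  rownames(expr) <- c("a", "b", "c")

  net <- correlationNetwork(expr, threshold = 1, mode = "absolute")
  expect_identical(nrow(net), 3L)          # all |r| = 1
  signed <- correlationNetwork(expr, threshold = 0.5, mode = "signed")
  expect_identical(nrow(signed), 1L)       # only the a~b pair has r = +1
  expect_identical(signed$from, 1L)
  expect_identical(signed$to, 2L)

  expect_error(correlationNetwork(expr[, 1:2], 0.5),
               "insufficient samples")
  expect_error(correlationNetwork(expr, 1.5), "threshold")
})

test_that("thresholded edges equal brute-force pairwise correlation", {
  expr <- genExpression(10, rep(0L, 20), seed = 23)
  net <- correlationNetwork(expr, threshold = 0.3)
  brute <- NULL
  for (i in 1:19) for (j in (i + 1):20) {
    r <- cor(expr[i, ], expr[j, ])
    if (abs(r) >= 0.3) brute <- rbind(brute, c(i, j, r))
  }
  if (is.null(brute)) brute <- matrix(numeric(0), 0, 3)
  expect_identical(cbind(net$from, net$to),
                   matrix(as.integer(brute[, 1:2]), ncol = 2))
  expect_equal(net$weight, brute[, 3])
})

test_that("zero-variance genes are skipped but stay in the universe", {
  expr <- rbind(matrix(rnorm(20), 2), rep(5, 10))
  rownames(expr) <- c("g1", "g2", "flat")
  net <- correlationNetwork(expr, threshold = 0)
  expect_false(any(c(net$from, net$to) == 3L))
  expect_identical(attr(net, "nVertices"), 3L)
})

test_that("Pearson edges are invariant to positive affine transforms", {
  expr <- genExpression(30, c(1, 1, 2, 2, 0, 0), mixing = 0.8, seed = 9)
  net1 <- correlationNetwork(expr, threshold = 0.4, mode = "signed")
  scaled <- expr * 3.7 + 11
  net2 <- correlationNetwork(scaled, threshold = 0.4, mode = "signed")
  expect_equal(net1, net2)
  # negating one gene flips the sign of its correlations
  flipped <- expr
  flipped[1, ] <- -flipped[1, ]
  net3 <- correlationNetwork(flipped, threshold = 0.4, mode = "signed")
  expect_false(any(net3$from == 1L & net3$to == 2L))
})

test_that("the seed's component subnetwork isolates its cluster", {
  # 3-clique {1,2,3} disjoint from edge {4,5}
  g <- buildCSR(edgeTable(c(1, 1, 2, 4), c(2, 3, 3, 5)),
                directed = FALSE)
  sub <- subnetworkWithSeed(g, 2)
  expect_identical(sub$vertices, 1:3)
  expect_identical(numEdges(sub$graph), 6L)

  iso <- buildCSR(edgeTable(1, 2, nVertices = 3), directed = FALSE)
  sub <- subnetworkWithSeed(iso, 3)
  expect_identical(sub$vertices, 3L)
  expect_identical(numEdges(sub$graph), 0L)

  expect_error(subnetworkWithSeed(iso, 9), "invalid vertex id")
  expect_error(subnetworkWithSeed(iso, "nope"), "invalid vertex id")

  # two ER clusters, no cross arcs: the seed's cluster comes back whole
  a <- genErdosRenyi(15, 0.5, seed = 3)
  b <- genErdosRenyi(12, 0.5, seed = 4)
  et <- edgeTable(c(a$from, b$from + 15L), c(a$to, b$to + 15L),
                  nVertices = 27)
  g2 <- buildCSR(et, directed = FALSE)
  expect_identical(subnetworkWithSeed(g2, 20)$vertices, 16:27)
  # the seed reaches every vertex of its subnetwork
  d <- distMatrix(bfsMulti(subnetworkWithSeed(g2, 20)$graph, 5))
  expect_true(all(is.finite(d)))
})

test_that("mean shortest-path statistics average finite ordered pairs", {
  path3 <- buildCSR(edgeTable(c(1, 2), c(2, 3)), directed = FALSE)
  st <- meanShortestPath(path3)
  expect_equal(st$meanDistance, 4 / 3)
  expect_identical(st$nPairsFinite, 6L)
  expect_identical(st$nPairsTotal, 6L)

  k4 <- buildCSR(edgeTable(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4)),
                 directed = FALSE)
  expect_equal(meanShortestPath(k4)$meanDistance, 1)

  lonely <- buildCSR(edgeTable(1, 2, nVertices = 3), directed = FALSE)
  st <- meanShortestPath(lonely)
  expect_identical(st$nPairsTotal, 6L)
  expect_identical(st$nPairsFinite, 2L)
  expect_equal(st$meanDistance, 1)
})

test_that("subnetwork distances never beat full-graph distances", {
  g <- randomGraph(41, 40, 0.12, directed = FALSE,
                   weightRange = c(0.1, 2))
  keep <- c(2L, 3L, 7L, 9L, 14L, 20L, 21L, 30L, 33L, 40L)
  sub <- inducedSubgraph(g, keep)
  dSub <- distMatrix(sssp(sub$graph, seq_along(keep), FALSE))
  dFull <- distMatrix(sssp(g, keep, FALSE))[, keep, drop = FALSE]
  expect_true(all(dSub >= unname(dFull) - 1e-9))
})
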