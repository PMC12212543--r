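pathGraph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

triangle <- matrix(1, 3, 3) - diag(3)

test_that("closed-form simple-path counts match exhaustive DFS enumeration", {
  # triangle: the 3-walk correction cancels everything
  ct <- countSimplePaths(triangle)
  expect_equal(ct$eta3, matrix(0, 3, 3))
  expect_equal(ct$eta2, triangle)  # one 2-path between each pair
  # 4-path: a-b-c-d has exactly one simple 3-path between its ends
  cp <- countSimplePaths(pathGraph(4))
  expect_equal(cp$eta3[1, 4], 1)
  expect_equal(cp$eta3[1, 2], 0)
  # edgeless
  ce <- countSimplePaths(matrix(0, 4, 4))
  expect_true(all(ce$eta1 == 0) && all(ce$eta2 == 0) && all(ce$eta3 == 0))
  # random graphs vs DFS oracle
  withr::with_seed(51, {
    for (i in 1:40) {
      A <- randomAdjacency(sample(3:8, 1), runif(1, 0.2, 0.7))
      got <- countSimplePaths(A)
      want <- dfsSimplePathCounts(A)
      expect_equal(got$eta1, want$eta1)
      expect_equal(got$eta2, want$eta2)
      expect_equal(got$eta3, want$eta3)
    }
  })
  expect_error(countSimplePaths(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("SLP weights the three path counts and vanishes on the diagonal", {
  # single edge
  s2 <- slpMatrix(countSimplePaths(pathGraph(2)))
  expect_equal(s2[1, 2], 0.6)
  # triangle with defaults: one 1-path + one 2-path
  st <- slpMatrix(countSimplePaths(triangle))
  expect_equal(st[1, 2], 0.95)
  expect_true(all(diag(st) == 0))
  expect_error(slpMatrix(countSimplePaths(triangle), c(0.2, 0.5, 0.3)),
               "a1 >= a2")
  expect_error(slpMatrix(countSimplePaths(triangle), c(0.6, 0.3, 0.3)),
               "sum to 1")
  # symmetry and non-negativity on a random subgraph
  withr::with_seed(52, A <- randomAdjacency(8, 0.4))
  S <- slpMatrix(countSimplePaths(A), c(0.7, 0.2, 0.1))
  expect_equal(S, t(S))
  expect_true(all(S >= 0))
})

test_that("local importance ranks the star center highest", {
  A <- matrix(0, 5, 5); A[1, -1] <- A[-1, 1] <- 1
  w <- localImportance(slpMatrix(countSimplePaths(A)))
  expect_equal(w[1], 4 * 0.6)                 # four length-1 paths
  expect_equal(w[2], 0.6 + 3 * 0.35)          # one 1-path + three 2-paths
  expect_equal(localImportance(matrix(0, 1, 1)), 0)
  withr::with_seed(53, A8 <- randomAdjacency(8, 0.35))
  counts <- dfsSimplePathCounts(A8)
  expect_equal(localImportance(slpMatrix(countSimplePaths(A8))),
               rowSums(0.6 * counts$eta1 + 0.35 * counts$eta2 +
                       0.05 * counts$eta3))
})

test_that("center update takes the most important node, ties to smallest index", {
  A <- matrix(0, 5, 5); A[1, -1] <- A[-1, 1] <- 1
  expect_equal(updateCenter(11:15, slpMatrix(countSimplePaths(A))), 11L)
  expect_equal(updateCenter(7L, matrix(0, 1, 1)), 7L)
  # cycle: all nodes equivalent
  cyc <- pathGraph(5); cyc[1, 5] <- cyc[5, 1] <- 1
  expect_equal(updateCenter(21:25, slpMatrix(countSimplePaths(cyc))), 21L)
})

test_that("refinement reaches a fixed point and stays there", {
  g <- toyThreeCommunities()
  ref <- refineCenters(g, c(1L, 9L, 17L), config = trainConfig(seed = 2))
  expect_equal(ref$trace$stopReason, "stable")
  expect_lte(length(ref$trace$iterations), 20)
  # re-running from the stable centers changes nothing
  again <- refineCenters(g, ref$centers, config = trainConfig(seed = 2))
  expect_identical(again$centers, ref$centers)
  # every center lies in its own community
  expect_equal(ref$partition[ref$centers], seq_along(ref$centers))
})

test_that("maxIter = 1 performs exactly one train/update pass", {
  g <- toyThreeCommunities()
  ref <- refineCenters(g, c(2L, 3L, 10L), config = trainConfig(seed = 4),
                       maxIter = 1L)
  expect_equal(length(ref$trace$iterations), 1)
  expect_true(ref$trace$stopReason %in% c("stable", "max_iter"))
})

test_that("adversarial centers in one clique are moved to distinct cliques", {
  g <- toyThreeCommunities()
  hits <- vapply(1:10, function(s) {
    ref <- refineCenters(g, c(2L, 3L, 10L), config = trainConfig(seed = s))
    length(unique(truthLabels(g)[ref$centers])) == 3L
  }, logical(1))
  expect_gte(sum(hits), 8)
})
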