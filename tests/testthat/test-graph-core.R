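test_that("edge lists parse with dedup, self-loop removal and symmetrization", {
  g <- readEdgeList(writeTempEdgeList(c("a b", "b c")))
  expect_equal(numNodes(g), 3)
  expect_equal(sum(adjacencyMatrix(g)) / 2, 2)
  expect_equal(nodeIds(g), c("a", "b", "c"))

  expect_message(
    g2 <- readEdgeList(writeTempEdgeList(c("a b", "b a", "a a"))),
    "self-loop"
  )
  expect_equal(numNodes(g2), 2)
  expect_equal(sum(adjacencyMatrix(g2)) / 2, 1)
})

test_that("a one-token line raises a parse error naming the line", {
  f <- writeTempEdgeList(c("a b", "c"))
  expect_error(readEdgeList(f), "line 2")
  expect_error(readEdgeList(tempfile()), "not found")
})

test_that("random noisy edge list equals a set-based construction oracle", {
  withr::with_seed(11, {
    ids <- letters[1:12]
    src <- sample(ids, 100, replace = TRUE)
    dst <- sample(ids, 100, replace = TRUE)
  })
  g <- suppressMessages(readEdgeList(
    writeTempEdgeList(paste(src, dst)), idPolicy = "reindex"))
  # oracle: unordered pair set, loops removed
  keep <- src != dst
  pairs <- unique(t(apply(cbind(src[keep], dst[keep]), 1, sort)))
  expected <- matrix(0, 12, 12, dimnames = list(sort(unique(c(src, dst))),
                                                sort(unique(c(src, dst)))))
  expected[pairs] <- 1
  expected <- pmax(expected, t(expected))
  expect_equal(unname(as.matrix(adjacencyMatrix(g))),
               unname(expected[nodeIds(g), nodeIds(g)]))
})

test_that("symmetrization is idempotent on an already-undirected list", {
  one <- readEdgeList(writeTempEdgeList(c("a b", "b c")))
  both <- readEdgeList(writeTempEdgeList(c("a b", "b a", "b c", "c b")))
  expect_equal(as.matrix(adjacencyMatrix(one)), as.matrix(adjacencyMatrix(both)))
})

test_that("attributes attach from dense TSV and MatrixMarket, shapes enforced", {
  g <- readEdgeList(writeTempEdgeList(c("a b", "b c")))
  f <- tempfile()
  write.table(matrix(0, 3, 2), f, row.names = FALSE, col.names = FALSE)
  g2 <- suppressMessages(readAttributes(f, g))
  expect_equal(dim(nodeFeatures(g2)), c(3L, 2L))

  withr::with_seed(4, X <- matrix(rbinom(50, 1, 0.4), 10, 5))
  fm <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), fm)
  g10 <- readEdgeList(writeTempEdgeList(paste0("x", 1:9, " x", 2:10)))
  expect_equal(unname(nodeFeatures(suppressMessages(readAttributes(fm, g10)))),
               unname(X * 1.0))

  fbad <- tempfile()
  write.table(matrix(0, 4, 2), fbad, row.names = FALSE, col.names = FALSE)
  expect_error(readAttributes(fbad, g), "expected 3 rows, found 4")
})

test_that("one-hot fallback is the identity pattern", {
  g <- readEdgeList(writeTempEdgeList(c("a b", "b c")))
  gf <- oneHotFeatures(g)
  expect_equal(nodeFeatures(gf), diag(3))
  expect_error(oneHotFeatures(gf), "already has")
  g1 <- communityGraph(matrix(0, 1, 1))
  expect_equal(nodeFeatures(oneHotFeatures(g1)), matrix(1, 1, 1))
})

test_that("normalized adjacency matches the dense closed form", {
  # single node: degree-with-self 1
  expect_equal(normalizeAdjacency(communityGraph(matrix(0, 1, 1))),
               matrix(1, 1, 1))
  # two connected nodes: all entries 1/2
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalizeAdjacency(communityGraph(A2)), matrix(0.5, 2, 2))
  # random graph vs brute-force D^{-1/2} (A+I) D^{-1/2}
  withr::with_seed(21, A <- randomAdjacency(15, 0.3))
  Ahat <- normalizeAdjacency(communityGraph(A))
  At <- A + diag(15)
  Dm <- diag(1 / sqrt(rowSums(At)))
  expect_equal(Ahat, Dm %*% At %*% Dm, tolerance = 1e-12)
  expect_lt(max(abs(Ahat - t(Ahat))), 1e-12)
  expect_true(all(diag(Ahat) > 0))
})

test_that("hop distances agree with per-pair BFS, sentinel for disconnected", {
  g <- readEdgeList(writeTempEdgeList(c("a b", "b c")))
  d <- shortestPathDistances(g)
  expect_equal(d[1, 3], 2L)

  g2 <- communityGraph(matrix(0, 2, 2))
  d2 <- shortestPathDistances(g2)
  expect_equal(d2[1, 2], 2L)  # sentinel N

  withr::with_seed(5, A <- randomAdjacency(12, 0.15))
  d3 <- shortestPathDistances(communityGraph(A))
  oracle <- bfsDistances(A)
  oracle[is.infinite(oracle)] <- 12
  expect_equal(d3, oracle, ignore_attr = TRUE)
  expect_equal(d3, t(d3), ignore_attr = TRUE)
  finite <- d3[d3 < attr(d3, "sentinel")]
  expect_true(all(finite <= 11))
})

test_that("membership files round-trip node ids and labels", {
  g <- readEdgeList(writeTempEdgeList(c("a b", "b c")))
  f <- tempfile()
  writeMembership(c(1L, 1L, 2L), g, f)
  back <- read.table(f, sep = "\t")
  expect_equal(back[[1]], c("a", "b", "c"))
  expect_equal(back[[2]], c(1L, 1L, 2L))

  fl <- tempfile()
  writeLines(c("b\tx", "a\tx", "c\ty"), fl)
  gl <- readLabels(fl, g)
  expect_equal(truthLabels(gl), c(1L, 1L, 2L))
})

test_that("graph container enforces its invariants", {
  expect_error(communityGraph(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(communityGraph(diag(2)), "diagonal")
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_error(communityGraph(A, features = matrix(0, 3, 2)), "2")
})
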