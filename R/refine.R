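#' @include gcn.R seeding.R
NULL

#' Closed-form simple-path counts of lengths 1-3
#'
#' For a simple undirected subgraph with adjacency A, the number of simple
#' paths (no repeated nodes) between distinct i and j is `A` for length 1,
#' `(A^2)_{ij}` for length 2 (a 2-walk between distinct endpoints cannot
#' repeat a node), and `(A^3)_{ij} - A_{ij}(deg_i + deg_j - 1)` for length
#' 3: the correction removes 3-walks that revisit an endpoint, which exist
#' only when i and j are adjacent. Diagonals are forced to zero.
#'
#' @param A n x n symmetric 0/1 matrix with zero diagonal.
#' @return list of matrices `eta1`, `eta2`, `eta3`.
#' @export
countSimplePaths <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || !isSymmetric(unname(A))) {
    stop("simple-path counting requires a square symmetric adjacency")
  }
  if (any(diag(A) != 0)) stop("adjacency diagonal must be zero")
  A2 <- A %*% A
  A3 <- A2 %*% A
  deg <- rowSums(A)
  eta3 <- A3 - A * (outer(deg, deg, `+`) - 1)
  diag(A2) <- 0
  diag(eta3) <- 0
  list(eta1 = A, eta2 = A2, eta3 = eta3)
}

#' Validate simple-path weights
#'
#' The three path-length weights must satisfy
#' \eqn{\alpha_1 \ge \alpha_2 \ge \alpha_3 \ge 0} and sum to 1. Default
#' `c(0.6, 0.35, 0.05)`.
#'
#' @param alpha numeric vector of length 3.
#' @return the validated vector.
#' @export
slpWeights <- function(alpha = c(0.6, 0.35, 0.05)) {
  if (length(alpha) != 3L || any(alpha < 0) ||
      alpha[1] < alpha[2] || alpha[2] < alpha[3] ||
      abs(sum(alpha) - 1) > 1e-9) {
    stop("path weights must satisfy a1 >= a2 >= a3 >= 0 and sum to 1")
  }
  alpha
}

#' Similarity based on local simple paths (SLP)
#'
#' Weighted count of simple paths of lengths 1-3 between every node pair
#' of an induced subgraph: \eqn{\alpha_1\eta^{(1)} + \alpha_2\eta^{(2)} +
#' \alpha_3\eta^{(3)}} off-diagonal, 0 on the diagonal.
#'
#' @param counts output of [countSimplePaths()].
#' @param alpha weights, see [slpWeights()].
#' @return n x n symmetric non-negative matrix.
#' @export
slpMatrix <- function(counts, alpha = c(0.6, 0.35, 0.05)) {
  alpha <- slpWeights(alpha)
  S <- alpha[1] * counts$eta1 + alpha[2] * counts$eta2 + alpha[3] * counts$eta3
  diag(S) <- 0
  S
}

#' Local structural importance
#'
#' \eqn{w(v_i | G_k) = \sum_j SLP(v_i, v_j | G_k)}: the row sums of the
#' SLP matrix. High for nodes at the core of the subgraph.
#'
#' @param slp matrix from [slpMatrix()].
#' @return numeric vector of per-node importances.
#' @export
localImportance <- function(slp) {
  rowSums(slp)
}

#' Updated structure center of a community subgraph
#'
#' The node of maximal local structural importance; ties go to the
#' smallest (global) node index.
#'
#' @param nodes integer vector of global node indices of the subgraph.
#' @param slp SLP matrix of the induced subgraph, in `nodes` order.
#' @return a single global node index.
#' @export
updateCenter <- function(nodes, slp) {
  stopifnot(length(nodes) >= 1, nrow(slp) == length(nodes))
  w <- localImportance(slp)
  nodes[order(-w, nodes)[1L]]
}

#' Iterative structure-center refinement
#'
#' Alternates two steps until the centers stabilize or `maxIter` is
#' reached: (a) train a fresh graph-convolutional classifier supervised by
#' the current K centers (one labeled node per community, seed =
#' `config$seed + r` at iteration r, so iterations are decoupled); (b)
#' partition the network by row-wise argmax, induce each community's
#' subgraph, and move each center to the node of maximal local structural
#' importance. Stability is positional: community k's center must be
#' unchanged. An empty community keeps its previous center (logged);
#' transiently empty partitions occur with bad seeds and usually recover.
#'
#' @param graph a [CommunityGraph-class]; one-hot features are substituted
#'   when the graph has no attributes.
#' @param centers integer vector of K initial center node indices.
#' @param alpha simple-path weights, see [slpWeights()].
#' @param config a [trainConfig()]; `config$seed` is the base seed of the
#'   per-iteration schedule.
#' @param maxIter iteration cap (default 20; runs typically stabilize
#'   within ~10).
#' @return list: final `centers`, `partition`, soft assignment `Z` of the
#'   last classifier, and `trace` (per-iteration centers and community
#'   sizes, plus `stopReason`).
#' @export
refineCenters <- function(graph, centers, alpha = c(0.6, 0.35, 0.05),
                          config = trainConfig(), maxIter = 20L) {
  alpha <- slpWeights(alpha)
  k <- length(centers)
  stopifnot(k >= 1, !anyDuplicated(centers))
  X <- nodeFeatures(graph)
  if (is.null(X)) X <- diag(numNodes(graph))
  Ahat <- normalizeAdjacency(graph)
  A <- as.matrix(adjacencyMatrix(graph))
  iters <- vector("list", maxIter)
  stopReason <- "max_iter"
  part <- NULL; Z <- NULL
  for (r in seq_len(maxIter)) {
    cfg <- config
    cfg$seed <- config$seed + r
    fit <- trainGCN(Ahat, X, as.list(centers), cfg)
    Z <- fit$Z
    part <- predictPartition(Z)
    newCenters <- centers
    for (kk in seq_len(k)) {
      nodes <- which(part == kk)
      if (!length(nodes)) next                      # keep previous center
      counts <- countSimplePaths(A[nodes, nodes, drop = FALSE])
      newCenters[kk] <- updateCenter(nodes, slpMatrix(counts, alpha))
    }
    iters[[r]] <- list(iteration = r, centers = newCenters,
                       communitySizes = tabulate(part, nbins = k),
                       emptyCommunities = sum(tabulate(part, nbins = k) == 0L))
    stable <- identical(newCenters, centers)
    centers <- newCenters
    if (stable) {
      stopReason <- "stable"
      iters <- iters[seq_len(r)]
      break
    }
  }
  if (stopReason == "max_iter") iters <- iters[seq_len(maxIter)]
  list(centers = centers, partition = part, Z = Z,
       trace = list(iterations = iters, stopReason = stopReason))
}
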