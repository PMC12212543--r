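#' @include AllClasses.R
NULL

#' Planted-partition (stochastic block model) graph with binary attributes
#'
#' Generates an assortative block-structured graph: within-block edges
#' with probability `pIn`, between-block edges with probability `pOut`
#' (`pOut < pIn`). Attributes emulate the sparse 0/1 word-vector regime of
#' citation networks: the `attrDim` coordinates are split into K
#' near-equal block-salient groups; a node's salient coordinates are
#' Bernoulli(`attrOnIn`), all others Bernoulli(`attrOnOut`), so similar-
#' attribute nodes tend to share a block (homophily). Block identities are
#' stored as ground-truth labels.
#'
#' @param blockSizes integer vector of K block sizes.
#' @param pIn,pOut within-/between-block edge probabilities,
#'   `0 <= pOut < pIn <= 1`.
#' @param attrDim attribute dimension F (0 for a non-attributed graph).
#' @param attrOnIn,attrOnOut activation probabilities of salient vs
#'   background coordinates.
#' @param seed integer seed; identical seeds reproduce the graph exactly.
#' @return a [CommunityGraph-class] with `truthLabels()` set.
#' @examples
#' g <- generateSBM(c(3, 3), pIn = 1, pOut = 0, attrDim = 0, seed = 1)
#' numNodes(g)   # two disjoint triangles
#' @export
generateSBM <- function(blockSizes, pIn, pOut, attrDim = 60L,
                        attrOnIn = 0.3, attrOnOut = 0.05, seed = 1L) {
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1)) {
    stop("need 0 <= pOut < pIn <= 1")
  }
  if (any(c(attrOnIn, attrOnOut) < 0) || any(c(attrOnIn, attrOnOut) > 1)) {
    stop("attribute probabilities must lie in [0, 1]")
  }
  stopifnot(all(blockSizes >= 1))
  k <- length(blockSizes)
  n <- sum(blockSizes)
  block <- rep(seq_len(k), times = blockSizes)
  withr::with_seed(as.integer(seed), {
    P <- matrix(pOut, n, n)
    P[outer(block, block, `==`)] <- pIn
    U <- matrix(runif(n * n), n, n)
    A <- (U < P) & upper.tri(P)
    A <- A | t(A)
    storage.mode(A) <- "double"
    X <- NULL
    if (attrDim > 0) {
      grp <- sort(rep_len(seq_len(k), attrDim))   # near-equal salient groups
      p <- matrix(attrOnOut, n, attrDim)
      p[outer(block, grp, `==`)] <- attrOnIn
      X <- matrix(rbinom(n * attrDim, 1L, as.vector(p)), n, attrDim)
    }
    communityGraph(A, nodeIds = sprintf("n%03d", seq_len(n)),
                   features = X, truthLabels = block)
  })
}

#' Deterministic three-clique toy network
#'
#' A fixed 24-node graph of three 8-cliques joined by single bridge edges
#' (1-9, 9-17, 17-1) forming a triangle between one designated node per
#' clique. Those three nodes are the unique density peaks, so K = 3
#' seeding provably selects one center per clique. Serves as a small,
#' fully separable instance for exercising seeding, refinement and the
#' full pipeline; the same edge list ships as a plain-text fixture.
#'
#' @return a [CommunityGraph-class] with 3-community ground truth.
#' @export
toyThreeCommunities <- function() {
  cliques <- list(1:8, 9:16, 17:24)
  edges <- do.call(rbind, lapply(cliques, function(v) t(combn(v, 2))))
  edges <- rbind(edges, c(1, 9), c(9, 17), c(17, 1))
  A <- matrix(0, 24, 24)
  A[edges] <- 1
  A <- pmax(A, t(A))
  communityGraph(A, nodeIds = sprintf("v%02d", 1:24),
                 truthLabels = rep(1:3, each = 8))
}
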