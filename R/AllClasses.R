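#' @include regcn-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

#' CommunityGraph: an undirected network with optional attributes and labels
#'
#' The central input container. Holds an ordered node set, a symmetric 0/1
#' adjacency matrix with zero diagonal, an optional non-negative node
#' attribute matrix (one row per node, in node order), and optional
#' ground-truth community labels used only for evaluation.
#'
#' Isolated nodes are allowed (they are reported by `show()`), self-loops
#' are not: the normalized propagation operator re-adds self-connections
#' explicitly.
#'
#' @slot nodeIds character vector of N distinct node identifiers; all
#'   matrices and vectors in the object follow this order.
#' @slot adjacency N x N sparse symmetric 0/1 `Matrix` with zero diagonal.
#' @slot features optional N x F non-negative numeric matrix of node
#'   attributes, or `NULL`.
#' @slot truthLabels optional integer vector of ground-truth community
#'   labels, or `NULL`.
#'
#' @seealso [communityGraph()], [readEdgeList()], [generateSBM()]
#' @export
setClass("CommunityGraph",
  representation(
    nodeIds = "character",
    adjacency = "Matrix",
    features = "matrixOrNULL",
    truthLabels = "integerOrNULL"
  )
)

setValidity("CommunityGraph", function(object) {
  n <- length(object@nodeIds)
  A <- object@adjacency
  msgs <- character()
  if (anyDuplicated(object@nodeIds)) {
    msgs <- c(msgs, "node identifiers must be distinct")
  }
  if (nrow(A) != n || ncol(A) != n) {
    msgs <- c(msgs, sprintf("adjacency is %dx%d but there are %d nodes",
                            nrow(A), ncol(A), n))
  } else {
    if (!Matrix::isSymmetric(A, tol = 0)) {
      msgs <- c(msgs, "adjacency must be symmetric")
    }
    if (any(Matrix::diag(A) != 0)) {
      msgs <- c(msgs, "adjacency diagonal must be zero (no self-loops)")
    }
    vals <- unique(A@x)
    if (length(vals) && !all(vals %in% c(0, 1))) {
      msgs <- c(msgs, "adjacency entries must be 0 or 1 (unweighted graph)")
    }
  }
  if (!is.null(object@features)) {
    if (nrow(object@features) != n) {
      msgs <- c(msgs, sprintf("feature matrix has %d rows, expected %d",
                              nrow(object@features), n))
    }
    if (any(object@features < 0)) {
      msgs <- c(msgs, "feature matrix must be non-negative")
    }
  }
  if (!is.null(object@truthLabels) && length(object@truthLabels) != n) {
    msgs <- c(msgs, sprintf("truth labels have length %d, expected %d",
                            length(object@truthLabels), n))
  }
  if (length(msgs)) msgs else TRUE
})

#' CommunityFit: the result of a community detection run
#'
#' Returned by [detectCommunities()]. Carries the hard partition, the soft
#' affiliation matrix of the final classifier, initial and refined structure
#' centers, the per-iteration refinement trace, the pseudo-label budget
#' actually used, agreement metrics when ground truth was available, and
#' the run configuration.
#'
#' @slot membership integer vector, one community label in 1..K per node.
#' @slot softAssignment N x K row-stochastic matrix of affiliation
#'   strengths from the final classifier.
#' @slot initialCenters integer vector of K node indices selected by the
#'   density-peaks criterion (position k carries pseudo-label k).
#' @slot centers integer vector of K refined center node indices.
#' @slot pseudoLabels list of K integer vectors: the pseudo-labeled
#'   training sets supervising the final classifier.
#' @slot tau integer: expanded nodes per pseudo-label.
#' @slot trace list: refinement trace (per-iteration centers, community
#'   sizes) and stop reason.
#' @slot metrics numeric vector (`acc`, `nmi`, `ari`) as fractions, or
#'   empty when no ground truth was supplied.
#' @slot config list of the run parameters.
#'
#' @seealso [detectCommunities()], [membership()], [seedCenters()]
#' @export
setClass("CommunityFit",
  representation(
    membership = "integer",
    softAssignment = "matrix",
    initialCenters = "integer",
    centers = "integer",
    pseudoLabels = "list",
    tau = "integer",
    trace = "list",
    metrics = "numeric",
    config = "list"
  )
)

setValidity("CommunityFit", function(object) {
  msgs <- character()
  n <- length(object@membership)
  if (nrow(object@softAssignment) != n) {
    msgs <- c(msgs, "soft assignment rows must match membership length")
  }
  k <- ncol(object@softAssignment)
  if (any(object@membership < 1L | object@membership > k)) {
    msgs <- c(msgs, "membership labels must lie in 1..K")
  }
  if (length(object@centers) != k) {
    msgs <- c(msgs, "need exactly one center per community")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CommunityGraph
#'
#' @param adjacency square symmetric 0/1 matrix (base or `Matrix`), zero
#'   diagonal.
#' @param nodeIds optional character identifiers; defaults to row names or
#'   `"v1".."vN"`.
#' @param features optional N x F non-negative attribute matrix.
#' @param truthLabels optional ground-truth labels (coerced to consecutive
#'   integers 1..A preserving order of first appearance).
#' @return a validated [CommunityGraph-class] object.
#' @examples
#' A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
#' g <- communityGraph(A)
#' numNodes(g)
#' @export
communityGraph <- function(adjacency, nodeIds = NULL, features = NULL,
                           truthLabels = NULL) {
  A <- Matrix::Matrix(adjacency, sparse = TRUE)
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  if (is.null(nodeIds)) {
    nodeIds <- rownames(adjacency)
    if (is.null(nodeIds)) nodeIds <- paste0("v", seq_len(nrow(A)))
  }
  dimnames(A) <- NULL
  if (!is.null(truthLabels)) {
    truthLabels <- as.integer(factor(truthLabels, levels = unique(truthLabels)))
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
  }
  methods::new("CommunityGraph", nodeIds = as.character(nodeIds),
               adjacency = A, features = features, truthLabels = truthLabels)
}
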