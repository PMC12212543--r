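#' @include AllClasses.R
NULL

#' Read an undirected graph from an edge list
#'
#' Parses a whitespace/tab-separated edge list (`src dst`, one edge per
#' line, `#` comments ignored). Duplicate edges are collapsed, self-loops
#' dropped (with a message), and directed inputs symmetrized: an edge is
#' present if listed in either direction. The method operates on simple
#' undirected graphs only.
#'
#' @param path path to the edge-list file.
#' @param idPolicy `"as-given"` keeps nodes in order of first appearance;
#'   `"reindex"` sorts identifiers lexicographically.
#' @return a [CommunityGraph-class] (without attributes or labels).
#' @export
readEdgeList <- function(path, idPolicy = c("as-given", "reindex")) {
  idPolicy <- match.arg(idPolicy)
  if (!file.exists(path)) {
    stop("cannot read edge list: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("edge list contains no data lines: ", path)
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) {
    stop(sprintf("parse error at line %d of %s: expected two tokens, found %d",
                 keep[bad[1]], path, lengths(toks)[bad[1]]))
  }
  src <- vapply(toks, `[`, character(1), 1L)
  dst <- vapply(toks, `[`, character(1), 2L)
  ids <- unique(c(rbind(src, dst)))
  if (idPolicy == "reindex") ids <- sort(ids)
  i <- match(src, ids)
  j <- match(dst, ids)
  loops <- i == j
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    i <- i[!loops]; j <- j[!loops]
  }
  n <- length(ids)
  lo <- pmin(i, j); hi <- pmax(i, j)
  pair <- unique(cbind(lo, hi))
  A <- Matrix::sparseMatrix(
    i = c(pair[, 1], pair[, 2]), j = c(pair[, 2], pair[, 1]),
    x = 1, dims = c(n, n)
  )
  communityGraph(A, nodeIds = ids)
}

#' Attach node attributes to a graph
#'
#' Reads a dense TSV (one row per node, graph node order) or a
#' MatrixMarket coordinate file (rows = nodes) and attaches it as the
#' attribute matrix.
#'
#' @param path attribute file.
#' @param graph a [CommunityGraph-class].
#' @return the graph with `nodeFeatures()` set.
#' @export
readAttributes <- function(path, graph) {
  stopifnot(is(graph, "CommunityGraph"))
  n <- numNodes(graph)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^%%MatrixMarket", first)) {
    X <- as.matrix(Matrix::readMM(path))
  } else {
    X <- as.matrix(read.table(path, header = FALSE, sep = "",
                              comment.char = "#"))
  }
  if (nrow(X) != n) {
    stop(sprintf("attribute shape mismatch: expected %d rows, found %d",
                 n, nrow(X)))
  }
  zero <- rowSums(X != 0) == 0
  if (any(zero)) message(sum(zero), " node(s) with all-zero attributes")
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  methods::initialize(graph, features = X)
}

#' Attach ground-truth labels to a graph
#'
#' Reads a two-column TSV `node_id<TAB>label`; every graph node must be
#' covered. Labels are used only for evaluation, never by the method.
#'
#' @param path label file.
#' @param graph a [CommunityGraph-class].
#' @return the graph with `truthLabels()` set.
#' @export
readLabels <- function(path, graph) {
  stopifnot(is(graph, "CommunityGraph"))
  tab <- read.table(path, header = FALSE, sep = "", comment.char = "#",
                    colClasses = "character")
  idx <- match(nodeIds(graph), tab[[1]])
  if (anyNA(idx)) {
    stop("label file missing node(s): ",
         paste(head(nodeIds(graph)[is.na(idx)], 5), collapse = ", "))
  }
  lab <- tab[[2]][idx]
  methods::initialize(graph,
    truthLabels = as.integer(factor(lab, levels = unique(lab))))
}

#' Write a membership file
#'
#' Writes `node_id<TAB>community` with communities numbered 1..K, in node
#' order.
#'
#' @param fit a [CommunityFit-class] or an integer membership vector.
#' @param graph the [CommunityGraph-class] that was partitioned.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMembership <- function(fit, graph, path) {
  memb <- if (is(fit, "CommunityFit")) membership(fit) else as.integer(fit)
  stopifnot(length(memb) == numNodes(graph))
  write.table(data.frame(node = nodeIds(graph), community = memb),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' One-hot fallback features
#'
#' For non-attributed networks the classifier input is initialized as
#' one-hot node indicators: row i of the N x N feature matrix has a single
#' 1 in column i.
#'
#' @param graph a [CommunityGraph-class] without attributes.
#' @return the graph with identity features attached.
#' @export
oneHotFeatures <- function(graph) {
  stopifnot(is(graph, "CommunityGraph"))
  if (!is.null(nodeFeatures(graph))) {
    stop("graph already has an attribute matrix")
  }
  methods::initialize(graph, features = diag(numNodes(graph)))
}

#' Symmetrically normalized adjacency with self-connections
#'
#' Computes the propagation operator of the graph convolution,
#' \eqn{\hat A = \tilde D^{-1/2} (A + I) \tilde D^{-1/2}} with
#' \eqn{\tilde D_{ii} = \sum_j (A + I)_{ij}}. Every diagonal entry is
#' strictly positive (an isolated node has \eqn{\tilde D_{ii} = 1}).
#'
#' @param graph a [CommunityGraph-class].
#' @return a dense symmetric N x N matrix.
#' @export
normalizeAdjacency <- function(graph) {
  stopifnot(is(graph, "CommunityGraph"))
  n <- numNodes(graph)
  Atil <- adjacencyMatrix(graph) + Matrix::Diagonal(n)
  dinv <- 1 / sqrt(Matrix::rowSums(Atil))
  as.matrix(Atil * outer(dinv, dinv))
}

#' All-pairs hop distances
#'
#' Unweighted shortest-path (breadth-first) hop counts between all node
#' pairs. Disconnected pairs receive the sentinel value N, larger than any
#' realizable hop distance, so downstream density-peak quantities stay
#' finite and maximal across components.
#'
#' @param graph a [CommunityGraph-class].
#' @return an integer N x N matrix with zero diagonal; `attr(,"sentinel")`
#'   holds the disconnected-pair value.
#' @export
shortestPathDistances <- function(graph) {
  stopifnot(is(graph, "CommunityGraph"))
  n <- numNodes(graph)
  g <- igraph::graph_from_adjacency_matrix(adjacencyMatrix(graph),
                                           mode = "undirected")
  d <- igraph::distances(g, algorithm = "unweighted")
  d[is.infinite(d)] <- n
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  attr(d, "sentinel") <- n
  d
}
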