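#' @include AllClasses.R
NULL

#' @rdname CommunityGraph-class
#' @param x,object a `CommunityGraph` or `CommunityFit`.
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname CommunityGraph-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname CommunityGraph-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname CommunityGraph-class
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @rdname CommunityGraph-class
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname CommunityFit-class
#' @param x a `CommunityFit`.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname CommunityFit-class
#' @export
setGeneric("softAssignment", function(x) standardGeneric("softAssignment"))

#' @rdname CommunityFit-class
#' @export
setGeneric("seedCenters", function(x) standardGeneric("seedCenters"))

#' @rdname CommunityFit-class
#' @export
setGeneric("refinementTrace", function(x) standardGeneric("refinementTrace"))

#' @rdname CommunityGraph-class
setMethod("nodeIds", "CommunityGraph", function(x) x@nodeIds)

#' @rdname CommunityGraph-class
setMethod("numNodes", "CommunityGraph", function(x) length(x@nodeIds))

#' @rdname CommunityGraph-class
setMethod("adjacencyMatrix", "CommunityGraph", function(x) x@adjacency)

#' @rdname CommunityGraph-class
setMethod("nodeFeatures", "CommunityGraph", function(x) x@features)

#' @rdname CommunityGraph-class
setMethod("truthLabels", "CommunityGraph", function(x) x@truthLabels)

#' @rdname CommunityFit-class
setMethod("membership", "CommunityFit", function(x) x@membership)

#' @rdname CommunityFit-class
setMethod("softAssignment", "CommunityFit", function(x) x@softAssignment)

#' @rdname CommunityFit-class
setMethod("seedCenters", "CommunityFit", function(x) x@centers)

#' @rdname CommunityFit-class
setMethod("refinementTrace", "CommunityFit", function(x) x@trace)

setMethod("show", "CommunityGraph", function(object) {
  n <- length(object@nodeIds)
  m <- sum(object@adjacency) / 2
  deg <- Matrix::rowSums(object@adjacency)
  cat(sprintf("CommunityGraph: %d nodes, %d edges\n", n, m))
  if (any(deg == 0)) {
    cat(sprintf("  %d isolated node(s)\n", sum(deg == 0)))
  }
  if (!is.null(object@features)) {
    cat(sprintf("  attributes: %d-dimensional\n", ncol(object@features)))
  } else {
    cat("  attributes: none (one-hot fallback will be used)\n")
  }
  if (!is.null(object@truthLabels)) {
    cat(sprintf("  ground truth: %d communities\n",
                length(unique(object@truthLabels))))
  }
  invisible(NULL)
})

setMethod("show", "CommunityFit", function(object) {
  k <- ncol(object@softAssignment)
  sizes <- tabulate(object@membership, nbins = k)
  cat(sprintf("CommunityFit: %d nodes partitioned into %d communities\n",
              length(object@membership), k))
  cat("  community sizes:", paste(sizes, collapse = " "), "\n")
  cat(sprintf("  centers: %s\n", paste(object@centers, collapse = " ")))
  cat(sprintf("  pseudo-labels per community (tau): %d\n", object@tau))
  cat(sprintf("  refinement: %d iteration(s), stopped (%s)\n",
              length(object@trace$iterations), object@trace$stopReason))
  if (length(object@metrics)) {
    cat(sprintf("  agreement with truth: ACC %.2f%%  NMI %.2f%%  ARI %.2f%%\n",
                100 * object@metrics[["acc"]], 100 * object@metrics[["nmi"]],
                100 * object@metrics[["ari"]]))
  }
  invisible(NULL)
})
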