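#' @include gcn.R
NULL

#' Lower bound on the pseudo-label budget
#'
#' A two-layer graph convolution propagates label information roughly
#' \eqn{\bar d^L} nodes per labeled seed, so covering the network needs
#' \eqn{K \tau \bar d^L \approx N}; the bound is
#' \eqn{\lceil N / (K \bar d^L) \rceil}, floored at 1. An edgeless graph
#' (zero mean degree) degenerates to N.
#'
#' @param n number of nodes.
#' @param k number of communities.
#' @param meanDegree average degree \eqn{\bar d = 2|E|/N}.
#' @param L number of convolution layers (default 2).
#' @return a positive integer.
#' @export
tauLowerBound <- function(n, k, meanDegree, L = 2L) {
  stopifnot(n >= 1, k >= 1, L >= 1, meanDegree >= 0)
  if (meanDegree == 0) {
    message("edgeless graph: tau lower bound degenerates to N")
    return(as.integer(n))
  }
  max(1L, as.integer(ceiling(n / (k * meanDegree^L))))
}

#' Affinity-based pseudo-label expansion
#'
#' Within each predicted community \eqn{V_k}, selects the `tau` nodes
#' whose affiliation strength to community k is closest to that of the
#' community's center, \eqn{|z_{x,k} - z_{c_k,k}|}. The center has
#' difference 0 and ties resolve in its favor, so it is always included;
#' remaining ties are broken by larger \eqn{z_{x,k}} (more confident
#' nodes), then smaller node index. `tau` is clipped to the community
#' size.
#'
#' @param Z N x K soft assignment.
#' @param partition integer labels consistent with `Z` (row-wise argmax).
#' @param centers K center node indices (position k = community k).
#' @param tau nodes per pseudo-label.
#' @return list of K disjoint integer vectors; set k carries pseudo-label
#'   k and contains the community's center.
#' @export
expandAffinity <- function(Z, partition, centers, tau) {
  Z <- as.matrix(Z)
  k <- length(centers)
  stopifnot(tau >= 1, ncol(Z) >= k)
  sets <- vector("list", k)
  for (kk in seq_len(k)) {
    ck <- centers[kk]
    vk <- which(partition == kk)
    if (!(ck %in% vk)) {
      message("center of community ", kk,
              " lies outside its predicted node set; force-included")
    }
    others <- setdiff(vk, ck)
    d <- abs(Z[others, kk] - Z[ck, kk])
    ranked <- others[order(d, -Z[others, kk], others)]
    sets[[kk]] <- c(ck, head(ranked, max(0L, tau - 1L)))
  }
  sets
}

#' Top-k pseudo-label expansion (comparison strategy)
#'
#' For each community, the `tau` nodes of largest affiliation strength
#' over the whole node set. A node wanted by several communities is kept
#' only where its affiliation is largest (ties to the smaller community
#' index), and the losing communities backfill with their next-ranked
#' nodes. Implemented as a single greedy sweep over all (node, community)
#' affiliations in decreasing order, which realizes exactly that
#' ownership-plus-backfill rule; with `tau = N` it reduces to the row-wise
#' argmax partition.
#'
#' @param Z N x K soft assignment.
#' @param tau nodes per pseudo-label.
#' @return list of K disjoint integer vectors.
#' @export
expandTopK <- function(Z, tau) {
  Z <- as.matrix(Z)
  n <- nrow(Z); k <- ncol(Z)
  stopifnot(tau >= 1)
  node <- rep(seq_len(n), times = k)
  comm <- rep(seq_len(k), each = n)
  ord <- order(-as.vector(Z), node, comm)
  sets <- rep(list(integer(0)), k)
  taken <- logical(n)
  filled <- integer(k)
  for (idx in ord) {
    v <- node[idx]; c <- comm[idx]
    if (taken[v] || filled[c] >= tau) next
    sets[[c]] <- c(sets[[c]], v)
    taken[v] <- TRUE
    filled[c] <- filled[c] + 1L
    if (all(filled >= tau) || all(taken)) break
  }
  sets
}
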