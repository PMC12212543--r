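#' @include graph-io.R
NULL

#' Local density
#'
#' \eqn{\rho_i} is the number of *other* nodes within cutoff distance
#' `dc` of node i. With `dc = 1` this is exactly the degree. The node
#' itself (distance 0) is excluded from the count.
#'
#' @param distances hop-distance matrix from [shortestPathDistances()].
#' @param dc cutoff distance, a positive integer (default 1).
#' @return integer vector of per-node densities.
#' @export
localDensity <- function(distances, dc = 1L) {
  if (!is.numeric(dc) || length(dc) != 1L || dc < 1) {
    stop("cutoff distance dc must be a positive integer")
  }
  as.integer(rowSums(distances <= dc) - 1L)
}

#' Relative distance to a denser node
#'
#' \eqn{\delta_i} is the minimum hop distance from node i to any node of
#' strictly higher local density. The single densest node takes the
#' maximum of its distance row instead. Density ties are broken by a
#' strict total order (density descending, then node index ascending) so
#' that exactly one node per graph receives the max-distance rule and tied
#' maxima within one dense region do not all inherit inflated values.
#'
#' @param distances hop-distance matrix.
#' @param rho densities from [localDensity()] on the same graph.
#' @return integer vector of per-node relative distances.
#' @export
relativeDistance <- function(distances, rho) {
  n <- length(rho)
  stopifnot(nrow(distances) == n)
  if (n == 1L) return(0L)
  ord <- order(-rho, seq_len(n))
  delta <- integer(n)
  top <- ord[1L]
  delta[top] <- max(distances[top, -top])
  for (k in 2:n) {
    v <- ord[k]
    delta[v] <- min(distances[v, ord[seq_len(k - 1L)]])
  }
  delta
}

#' Structural centrality
#'
#' \eqn{\phi_i = \rho_i \cdot \delta_i}: large only for density peaks,
#' i.e. nodes that are locally dense *and* far from any denser node.
#'
#' @param rho,delta equal-length vectors from [localDensity()] and
#'   [relativeDistance()].
#' @return numeric vector of per-node centralities.
#' @export
structuralCentrality <- function(rho, delta) {
  if (length(rho) != length(delta)) {
    stop(sprintf("length mismatch: rho has %d entries, delta has %d",
                 length(rho), length(delta)))
  }
  as.numeric(rho) * as.numeric(delta)
}

#' Density-peaks profile of a graph
#'
#' Convenience wrapper computing \eqn{\rho}, \eqn{\delta} and
#' \eqn{\phi = \rho\delta} for every node.
#'
#' @param graph a [CommunityGraph-class].
#' @param dc cutoff distance.
#' @return a data.frame with columns `node`, `rho`, `delta`, `phi`.
#' @export
centralityProfile <- function(graph, dc = 1L) {
  d <- shortestPathDistances(graph)
  rho <- localDensity(d, dc)
  delta <- relativeDistance(d, rho)
  data.frame(node = nodeIds(graph), rho = rho, delta = delta,
             phi = structuralCentrality(rho, delta))
}

#' Select K initial structure centers
#'
#' Picks the K nodes of largest structural centrality, ties broken toward
#' the smaller node index; position k of the result carries pseudo-label
#' k. Output is in descending centrality order.
#'
#' @param phi per-node centralities.
#' @param k number of communities, `1 <= k <= N`.
#' @return integer vector of K distinct node indices.
#' @export
selectInitialCenters <- function(phi, k) {
  n <- length(phi)
  if (k < 1L || k > n) {
    stop(sprintf("k must lie in 1..%d, got %s", n, k))
  }
  order(-phi, seq_len(n))[seq_len(k)]
}
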