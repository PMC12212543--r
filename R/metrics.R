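#' @include AllClasses.R
NULL

#' Contingency table of two partitions
#'
#' Entry (a, b) counts the nodes assigned to truth community a and
#' predicted community b. Entries sum to N; row/column sums are the
#' community sizes.
#'
#' @param truth,pred equal-length label vectors over the same node set.
#' @return an A x K integer matrix.
#' @export
contingencyTable <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop(sprintf("partition length mismatch: %d vs %d",
                 length(truth), length(pred)))
  }
  tab <- table(factor(truth), factor(pred))
  matrix(as.integer(tab), nrow(tab), ncol(tab))
}

#' Clustering accuracy with optimal label mapping
#'
#' Fraction of correctly labeled nodes under the injective predicted-to-
#' truth label mapping that maximizes agreement, found by maximum-weight
#' bipartite matching (Hungarian-equivalent assignment) on the contingency
#' table. Invariant under any relabeling of the predicted communities and
#' always at least 1/K.
#'
#' @param truth,pred label vectors.
#' @return a fraction in (0, 1].
#' @export
clusteringAccuracy <- function(truth, pred) {
  cont <- contingencyTable(truth, pred)
  n <- sum(cont)
  a <- nrow(cont); b <- ncol(cont)
  s <- max(a, b)
  sq <- matrix(0, s, s)
  sq[seq_len(a), seq_len(b)] <- cont
  el <- rbind(rep(seq_len(s), times = s), s + rep(seq_len(s), each = s))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, s), rep(TRUE, s)),
                                    as.vector(el), directed = FALSE)
  # +1 keeps all weights positive so the optimum is a perfect matching
  m <- igraph::max_bipartite_match(g, weights = as.vector(sq) + 1)
  matched <- m$matching[seq_len(s)] - s
  sum(sq[cbind(seq_len(s), matched)]) / n
}

#' Normalized mutual information
#'
#' Arithmetic-mean normalization \eqn{2 I(P, C) / (H(P) + H(C))} computed
#' from the contingency sums, with 0 log 0 terms treated as 0. Degenerate
#' cases: both partitions single-cluster returns 1 (identical trivial
#' partitions); exactly one single-cluster partition returns 0 (zero
#' entropy in the denominator contributes no shared information).
#'
#' @param truth,pred label vectors.
#' @return a value in `[0, 1]`.
#' @export
clusteringNMI <- function(truth, pred) {
  cont <- contingencyTable(truth, pred)
  n <- sum(cont)
  ra <- rowSums(cont); cb <- colSums(cont)
  ha <- -sum(ifelse(ra > 0, ra * log(ra / n), 0))
  hb <- -sum(ifelse(cb > 0, cb * log(cb / n), 0))
  if (ha + hb == 0) return(1)        # both trivial, hence identical
  if (ha == 0 || hb == 0) return(0)
  nz <- which(cont > 0, arr.ind = TRUE)
  mi <- sum(cont[nz] * log(cont[nz] * n / (ra[nz[, 1]] * cb[nz[, 2]])))
  2 * mi / (ha + hb)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement corrected for chance, computed from the
#' contingency table's choose-2 sums. Equals 1 only for identical
#' partitions and is near 0 for independent random partitions; the
#' formula can return negative values for worse-than-random agreement,
#' and such values are reported as-is rather than clipped.
#'
#' @param truth,pred label vectors over at least 2 nodes.
#' @return a value no greater than 1.
#' @export
clusteringARI <- function(truth, pred) {
  cont <- contingencyTable(truth, pred)
  n <- sum(cont)
  stopifnot(n >= 2)
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(cont))
  sumA <- sum(ch2(rowSums(cont)))
  sumB <- sum(ch2(colSums(cont)))
  expected <- sumA * sumB / ch2(n)
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(ifelse(sumIJ == expected, 1, 0))
  (sumIJ - expected) / (maxIdx - expected)
}

#' Score a predicted partition against ground truth
#'
#' @param truth,pred label vectors.
#' @param percent report on the 0-100 scale (as in benchmark tables)
#'   instead of fractions.
#' @return named numeric vector `acc`, `nmi`, `ari`.
#' @export
scorePartition <- function(truth, pred, percent = FALSE) {
  out <- c(acc = clusteringAccuracy(truth, pred),
           nmi = clusteringNMI(truth, pred),
           ari = clusteringARI(truth, pred))
  if (percent) out * 100 else out
}
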