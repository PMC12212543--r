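# Independent brute-force oracles used to check the closed-form /
# library-backed implementations. Deliberately naive.

# symmetric 0/1 adjacency of an Erdos-Renyi draw
randomAdjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

# per-pair breadth-first hop counts; Inf for disconnected pairs
bfsDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] == 1 & is.infinite(dist))
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# exhaustive DFS enumeration of simple paths of lengths 1..3
dfsSimplePathCounts <- function(A) {
  n <- nrow(A)
  out <- list(eta1 = matrix(0, n, n), eta2 = matrix(0, n, n),
              eta3 = matrix(0, n, n))
  extend <- function(path) {
    len <- length(path) - 1L
    if (len >= 1L) {
      key <- paste0("eta", len)
      i <- path[1]; j <- path[length(path)]
      out[[key]][i, j] <<- out[[key]][i, j] + 1
    }
    if (len == 3L) return(invisible(NULL))
    for (v in which(A[path[length(path)], ] == 1)) {
      if (!(v %in% path)) extend(c(path, v))
    }
  }
  for (s in seq_len(n)) extend(s)
  lapply(out, function(M) { diag(M) <- 0; M })
}

# all permutations of 1..n (n small)
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exhaustive-permutation best-mapping accuracy
permutationAccuracy <- function(truth, pred) {
  cont <- table(factor(truth), factor(pred))
  s <- max(dim(cont))
  sq <- matrix(0, s, s)
  sq[seq_len(nrow(cont)), seq_len(ncol(cont))] <- cont
  best <- 0
  for (p in allPerms(s)) {
    best <- max(best, sum(sq[cbind(p, seq_len(s))]))
  }
  best / length(truth)
}

# adjusted Rand index by explicit pair counting over all node pairs
pairCountARI <- function(truth, pred) {
  n <- length(truth)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- truth[i] == truth[j]; sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) c_ <- c_ + 1
    else d <- d + 1
  }
  den <- (a + b) * (b + d) + (a + c_) * (c_ + d)
  if (den == 0) return(1)
  2 * (a * d - b * c_) / den
}

# density-peaks relative distance straight from its definition, with the
# same strict (rho desc, index asc) tie order
relativeDistanceOracle <- function(D, rho) {
  n <- length(rho)
  denser <- function(j, i) {
    rho[j] > rho[i] || (rho[j] == rho[i] && j < i)
  }
  sapply(seq_len(n), function(i) {
    above <- Filter(function(j) denser(j, i), setdiff(seq_len(n), i))
    if (!length(above)) max(D[i, -i]) else min(D[i, above])
  })
}

writeTempEdgeList <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
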