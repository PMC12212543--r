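#' @include graph-io.R
NULL

#' Training configuration for the graph convolutional classifier
#'
#' The canonical two-layer settings: 16 hidden units, Adam with learning
#' rate 0.01, 200 epochs, weight decay 5e-4 on both layers, no dropout
#' (omitted so that a fixed seed reproduces runs exactly).
#'
#' @param hiddenDim hidden layer width D.
#' @param learningRate Adam step size.
#' @param epochs number of full-batch updates.
#' @param weightDecay L2 penalty coefficient applied to both weight
#'   matrices.
#' @param seed integer seed for weight initialization.
#' @return a list of class `trainConfig`.
#' @export
trainConfig <- function(hiddenDim = 16L, learningRate = 0.01, epochs = 200L,
                        weightDecay = 5e-4, seed = 42L) {
  stopifnot(hiddenDim >= 1, learningRate > 0, epochs >= 0, weightDecay >= 0)
  structure(list(hiddenDim = as.integer(hiddenDim),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 weightDecay = weightDecay, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Initialize classifier weights
#'
#' Glorot-uniform entries, \eqn{U(-l, l)} with
#' \eqn{l = \sqrt{6/(fan_{in}+fan_{out})}}, drawn from a seeded generator;
#' the caller's RNG state is untouched.
#'
#' @param nFeatures input dimension F.
#' @param hiddenDim hidden dimension D.
#' @param k output dimension (number of communities).
#' @param seed integer seed.
#' @return list with matrices `W0` (F x D) and `W1` (D x K).
#' @export
initGCNParams <- function(nFeatures, hiddenDim, k, seed) {
  stopifnot(nFeatures >= 1, hiddenDim >= 1, k >= 1)
  glorot <- function(fin, fout) {
    l <- sqrt(6 / (fin + fout))
    matrix(runif(fin * fout, -l, l), fin, fout)
  }
  withr::with_seed(as.integer(seed), {
    list(W0 = glorot(nFeatures, hiddenDim), W1 = glorot(hiddenDim, k))
  })
}

rowSoftmax <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

#' Forward pass of the two-layer graph convolution
#'
#' \eqn{Z = softmax(\hat A\, ReLU(\hat A X W^{(0)})\, W^{(1)})}, rows of Z
#' summing to 1; entry \eqn{z_{i,k}} is the affiliation strength of node i
#' to community k.
#'
#' @param Ahat normalized adjacency from [normalizeAdjacency()].
#' @param X N x F feature matrix.
#' @param params weight list from [initGCNParams()].
#' @return N x K row-stochastic matrix.
#' @export
gcnForward <- function(Ahat, X, params) {
  if (ncol(Ahat) != nrow(X) || ncol(X) != nrow(params$W0) ||
      ncol(params$W0) != nrow(params$W1)) {
    stop("shape mismatch in forward pass: need N x F, F x D, D x K chain")
  }
  H1 <- pmax(Ahat %*% X %*% params$W0, 0)
  rowSoftmax(Ahat %*% H1 %*% params$W1)
}

#' Train the classifier on pseudo-labeled nodes
#'
#' Minimizes the summed cross-entropy
#' \eqn{J = -\sum_k \sum_{v_i \in S_k} \log z_{i,k}} over the
#' pseudo-labeled sets by full-batch Adam, starting from fresh
#' Glorot weights drawn with `config$seed`. The L2 penalty
#' (`weightDecay`) enters the gradients of both layers.
#'
#' @param Ahat normalized adjacency (dense).
#' @param X N x F feature matrix.
#' @param pseudo list of K integer vectors of node indices; set k carries
#'   pseudo-label k and must be non-empty.
#' @param config a [trainConfig()].
#' @return list with `params`, the final soft assignment `Z`, and the
#'   per-epoch cross-entropy `lossTrace`.
#' @export
trainGCN <- function(Ahat, X, pseudo, config = trainConfig()) {
  k <- length(pseudo)
  empty <- which(lengths(pseudo) == 0L)
  if (length(empty)) {
    stop("supervision error: community ", empty[1], " has no pseudo-labeled node")
  }
  n <- nrow(Ahat)
  stopifnot(all(unlist(pseudo) >= 1), all(unlist(pseudo) <= n))
  X <- as.matrix(X)
  params <- initGCNParams(ncol(X), config$hiddenDim, k, config$seed)
  sup <- unlist(pseudo, use.names = FALSE)
  supLab <- rep(seq_len(k), lengths(pseudo))
  M1 <- Ahat %*% X                      # fixed across epochs
  Y <- matrix(0, n, k)
  Y[cbind(sup, supLab)] <- 1

  # Adam state
  lr <- config$learningRate; wd <- config$weightDecay
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m0 <- v0 <- params$W0 * 0; m1 <- v1 <- params$W1 * 0
  loss <- numeric(config$epochs)

  forward <- function(p) {
    P1 <- M1 %*% p$W0
    H1 <- pmax(P1, 0)
    M2 <- Ahat %*% H1
    list(P1 = P1, M2 = M2, Z = rowSoftmax(M2 %*% p$W1))
  }
  for (ep in seq_len(config$epochs)) {
    fw <- forward(params)
    loss[ep] <- -sum(log(pmax(fw$Z[cbind(sup, supLab)], 1e-300)))
    G <- fw$Z * 0
    G[sup, ] <- fw$Z[sup, , drop = FALSE] - Y[sup, , drop = FALSE]
    gW1 <- crossprod(fw$M2, G) + wd * params$W1
    gP1 <- (Ahat %*% (G %*% t(params$W1))) * (fw$P1 > 0)
    gW0 <- crossprod(M1, gP1) + wd * params$W0
    m0 <- b1 * m0 + (1 - b1) * gW0; v0 <- b2 * v0 + (1 - b2) * gW0^2
    m1 <- b1 * m1 + (1 - b1) * gW1; v1 <- b2 * v1 + (1 - b2) * gW1^2
    c1 <- 1 - b1^ep; c2 <- 1 - b2^ep
    params$W0 <- params$W0 - lr * (m0 / c1) / (sqrt(v0 / c2) + eps)
    params$W1 <- params$W1 - lr * (m1 / c1) / (sqrt(v1 / c2) + eps)
  }
  list(params = params, Z = as.matrix(forward(params)$Z), lossTrace = loss)
}

#' Hard partition from soft affiliations
#'
#' Per-row argmax of the affiliation matrix; exact ties go to the smaller
#' community index. Empty communities are permitted in the result.
#'
#' @param Z N x K row-stochastic matrix.
#' @return integer vector of labels in 1..K.
#' @export
predictPartition <- function(Z) {
  max.col(as.matrix(Z), ties.method = "first")
}
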