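#' Numerically stable logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, computed without overflow for large |x|.
#'
#' @param x numeric vector/matrix.
#' @return values in (0, 1) (0/1 exactly only at -Inf/Inf).
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Construct an RBM with small random weights
#'
#' @param nVis,nHid visible/hidden unit counts.
#' @param visibleKind "bernoulli" or "gaussian".
#' @param seed integer seed for the weight draw.
#' @param sdInit sd of the initial weights.
#' @return an [RBM-class].
#' @export
rbm <- function(nVis, nHid, visibleKind = c("bernoulli", "gaussian"),
                seed = 1L, sdInit = 0.01) {
  visibleKind <- match.arg(visibleKind)
  W <- withLocalSeed(seed, matrix(rnorm(nVis * nHid, sd = sdInit), nVis, nHid))
  new("RBM", W = W, bVis = rep(0, nVis), bHid = rep(0, nHid),
      visibleKind = visibleKind, beta = rep(1, nVis))
}

#' Hidden conditional probabilities
#'
#' `P(h_j = 1 | v) = sigmoid(bHid_j + W[, j] . v)`, row-wise for a matrix of
#' visible configurations.
#'
#' @param object an [RBM-class].
#' @param v visible vector or n x nVis matrix.
#' @return n x nHid matrix of probabilities.
#' @export
hiddenActivation <- function(object, v) {
  v <- rbind(v)
  if (ncol(v) != nrow(object@W))
    stop("visible dimension mismatch: got ", ncol(v), ", expected ",
         nrow(object@W))
  sigmoid(sweep(v %*% object@W, 2, object@bHid, "+"))
}

#' Visible conditional probabilities or means
#'
#' Bernoulli visibles: `P(v_i = 1 | h) = sigmoid(bVis_i + W[i, ] . h)`.
#' Gaussian visibles: the conditional mean `bVis + W h` (the conditional is
#' Normal with diagonal precision `beta`).
#'
#' @param object an [RBM-class].
#' @param h hidden vector or n x nHid matrix.
#' @return n x nVis matrix of probabilities (bernoulli) or means (gaussian).
#' @export
visibleActivation <- function(object, h) {
  h <- rbind(h)
  if (ncol(h) != ncol(object@W))
    stop("hidden dimension mismatch: got ", ncol(h), ", expected ",
         ncol(object@W))
  pre <- sweep(h %*% t(object@W), 2, object@bVis, "+")
  if (object@visibleKind == "bernoulli") sigmoid(pre) else pre
}

#' RBM energy of a joint configuration
#'
#' Bernoulli: `E(v, h) = -bVis.v - bHid.h - v' W h`. Gaussian visibles:
#' `E(v, h) = sum(beta (v - bVis)^2) / 2 - bHid.h - v' W h`.
#'
#' @param object an [RBM-class].
#' @param v,h visible/hidden vectors.
#' @return scalar energy.
#' @export
rbmEnergy <- function(object, v, h) {
  inter <- drop(v %*% object@W %*% h)
  if (object@visibleKind == "bernoulli") {
    -sum(object@bVis * v) - sum(object@bHid * h) - inter
  } else {
    sum(object@beta * (v - object@bVis)^2) / 2 - sum(object@bHid * h) - inter
  }
}

#' Unnormalized marginal probability of a visible configuration
#'
#' `P*(v) = sum_h exp(-E(v, h))`, computed analytically via the free energy
#' (the hidden sum factorizes over units). Comparable to brute-force
#' enumeration of all hidden states for small models.
#'
#' @param object an [RBM-class].
#' @param v visible vector or matrix of rows.
#' @return unnormalized probabilities, one per row.
#' @export
rbmUnnormalizedProb <- function(object, v) {
  exp(-rbmFreeEnergy(object, v))
}

#' RBM free energy
#'
#' `F(v) = -log sum_h exp(-E(v, h))`; for Bernoulli hiddens,
#' `F(v) = energy_vis(v) - sum_j log(1 + exp(bHid_j + W[, j] . v))`.
#'
#' @param object an [RBM-class].
#' @param v visible vector or matrix of rows.
#' @return numeric vector of free energies.
#' @export
rbmFreeEnergy <- function(object, v) {
  v <- rbind(v)
  pre <- sweep(v %*% object@W, 2, object@bHid, "+")
  softplus <- ifelse(pre > 30, pre, log1p(exp(pre)))
  visTerm <- if (object@visibleKind == "bernoulli") {
    -drop(v %*% object@bVis)
  } else {
    rowSums(sweep((sweep(v, 2, object@bVis, "-"))^2, 2, object@beta, "*")) / 2
  }
  unname(visTerm - rowSums(softplus))
}

#' Train an RBM with contrastive divergence (CD-k)
#'
#' Minibatch CD-k: the positive phase uses the data and its hidden
#' probabilities; the negative phase runs k alternating Gibbs steps (hidden
#' states sampled, visible reconstructed by its conditional mean — a standard
#' stabilization, also appropriate for Gaussian visibles), with probabilities
#' rather than samples in the final statistics. Deterministic per seed.
#'
#' @param data n x nVis matrix; rows in [0, 1] for bernoulli visibles,
#'   standardized for gaussian.
#' @param nHidden number of hidden units.
#' @param k CD steps (>= 1).
#' @param lr learning rate (0 leaves parameters unchanged).
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param visibleKind "bernoulli" or "gaussian".
#' @param weightDecay L2 penalty coefficient on W.
#' @param seed integer seed.
#' @param init optional [RBM-class] to start from.
#' @return trained [RBM-class].
#' @export
trainRBMCD <- function(data, nHidden, k = 1L, lr = 0.05, epochs = 10L,
                       batchSize = 32L, visibleKind = c("bernoulli", "gaussian"),
                       weightDecay = 0, seed = 1L, init = NULL) {
  visibleKind <- match.arg(visibleKind)
  if (k < 1L) stop("CD steps k must be >= 1")
  data <- as.matrix(data)
  nVis <- ncol(data)
  model <- if (is.null(init)) rbm(nVis, nHidden, visibleKind,
                                  seed = deriveSeed(seed, 3L)) else init
  W <- model@W; bV <- model@bVis; bH <- model@bHid
  n <- nrow(data)
  withLocalSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + batchSize - 1L, n)]
        v0 <- data[idx, , drop = FALSE]
        m <- length(idx)
        h0 <- sigmoid(sweep(v0 %*% W, 2, bH, "+"))
        vk <- v0; hk <- h0
        for (step in seq_len(k)) {
          hs <- matrix(as.numeric(runif(length(hk)) < hk), m, nHidden)
          pre <- sweep(hs %*% t(W), 2, bV, "+")
          vk <- if (visibleKind == "bernoulli") sigmoid(pre) else pre
          hk <- sigmoid(sweep(vk %*% W, 2, bH, "+"))
        }
        gW <- (crossprod(v0, h0) - crossprod(vk, hk)) / m - weightDecay * W
        W <- W + lr * gW
        bV <- bV + lr * colMeans(v0 - vk)
        bH <- bH + lr * colMeans(h0 - hk)
      }
    }
  })
  new("RBM", W = W, bVis = bV, bHid = bH, visibleKind = visibleKind,
      beta = model@beta)
}

#' Exact log-likelihood of data under a small RBM
#'
#' Brute-force partition function over all 2^nVis visible states (bernoulli)
#' using the analytic hidden marginalization; feasible only for toy models.
#'
#' @param object an [RBM-class] with bernoulli visibles and few units.
#' @param data n x nVis binary matrix.
#' @return mean log-likelihood per row.
#' @export
rbmExactLogLik <- function(object, data) {
  nVis <- nrow(object@W)
  stopifnot(object@visibleKind == "bernoulli", nVis <= 20)
  allV <- as.matrix(expand.grid(rep(list(c(0, 1)), nVis)))
  fAll <- rbmFreeEnergy(object, allV)
  logZ <- max(-fAll) + log(sum(exp(-fAll - max(-fAll))))
  mean(-rbmFreeEnergy(object, data) - logZ)
}
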