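## Stacked autoencoder for optional feature compression.
##
## Encoder E_i = f(W_i E_{i-1} + b_i) with logistic-sigmoid f; the mirrored
## decoder uses sigmoid hidden layers and an identity output layer (the
## features are real-valued). Trained by minibatch SGD on the mean squared
## reconstruction error  L = sum((Xhat - X)^2) / N.

#' Mean squared reconstruction loss
#'
#' `sum((xhat - x)^2) / N` with N the number of rows (batch size).
#'
#' @param xhat,x matrices of identical shape.
#' @return scalar loss.
#' @export
aeLoss <- function(xhat, x) {
  sum((xhat - x)^2) / nrow(rbind(x))
}

aeForwardFull <- function(model, X) {
  X <- rbind(X)
  enc <- list()
  cur <- X
  for (l in seq_along(model@encW)) {
    cur <- sigmoid(sweep(cur %*% model@encW[[l]], 2, model@encB[[l]], "+"))
    enc[[l]] <- cur
  }
  dec <- list()
  nd <- length(model@decW)
  for (l in seq_len(nd)) {
    pre <- sweep(cur %*% model@decW[[l]], 2, model@decB[[l]], "+")
    cur <- if (l < nd) sigmoid(pre) else pre   # identity output layer
    dec[[l]] <- cur
  }
  list(enc = enc, dec = dec, xhat = cur)
}

#' Encode data to the bottleneck representation
#' @param model an [AEModel-class].
#' @param X n x p input matrix.
#' @return n x bottleneck matrix (the top encoding layer E_n).
#' @export
aeEncode <- function(model, X) {
  aeForwardFull(model, X)$enc[[length(model@encW)]]
}

#' Reconstruct data through the full autoencoder
#' @param model an [AEModel-class].
#' @param X n x p input matrix.
#' @return n x p reconstruction.
#' @export
aeReconstruct <- function(model, X) {
  aeForwardFull(model, X)$xhat
}

#' Train a stacked autoencoder
#'
#' `layerDims` is the encoder chain including the input dimension, strictly
#' decreasing (e.g. `c(10, 6, 2)` for a 2-unit bottleneck); the decoder
#' mirrors it. Deterministic per seed.
#'
#' @param X n x p data matrix.
#' @param layerDims strictly decreasing integer chain, `layerDims[1] = p`.
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed integer seed.
#' @return an [AEModel-class].
#' @export
trainAutoencoder <- function(X, layerDims, lr = 0.05, epochs = 50L,
                             batchSize = 32L, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(layerDims[1] == ncol(X), all(diff(layerDims) < 0))
  dims <- as.integer(layerDims)
  ne <- length(dims) - 1L
  decDims <- rev(dims)
  withLocalSeed(seed, {
    encW <- lapply(seq_len(ne), function(l)
      matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(1 / dims[l])),
             dims[l], dims[l + 1]))
    encB <- lapply(seq_len(ne), function(l) rep(0, dims[l + 1]))
    decW <- lapply(seq_len(ne), function(l)
      matrix(rnorm(decDims[l] * decDims[l + 1], sd = sqrt(1 / decDims[l])),
             decDims[l], decDims[l + 1]))
    decB <- lapply(seq_len(ne), function(l) rep(0, decDims[l + 1]))
    model <- new("AEModel", encW = encW, encB = encB, decW = decW,
                 decB = decB, dims = dims)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (s in seq(1L, n, by = batchSize)) {
        idx <- ord[s:min(s + batchSize - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        m <- nrow(xb)
        fw <- aeForwardFull(model, xb)
        # gradient of sum((xhat - x)^2)/m
        delta <- 2 * (fw$xhat - xb) / m
        # decoder backward
        for (l in rev(seq_len(ne))) {
          below <- if (l == 1L) fw$enc[[ne]] else fw$dec[[l - 1L]]
          gW <- crossprod(below, delta)
          gB <- colSums(delta)
          deltaPrev <- delta %*% t(model@decW[[l]])
          if (l > 1L) deltaPrev <- deltaPrev * fw$dec[[l - 1L]] * (1 - fw$dec[[l - 1L]])
          model@decW[[l]] <- model@decW[[l]] - lr * gW
          model@decB[[l]] <- model@decB[[l]] - lr * gB
          delta <- deltaPrev
        }
        # encoder backward (delta currently w.r.t. E_n pre-sigmoid input)
        delta <- delta * fw$enc[[ne]] * (1 - fw$enc[[ne]])
        for (l in rev(seq_len(ne))) {
          below <- if (l == 1L) xb else fw$enc[[l - 1L]]
          gW <- crossprod(below, delta)
          gB <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(model@encW[[l]]) *
              fw$enc[[l - 1L]] * (1 - fw$enc[[l - 1L]])
          }
          model@encW[[l]] <- model@encW[[l]] - lr * gW
          model@encB[[l]] <- model@encB[[l]] - lr * gB
        }
      }
    }
    model
  })
}
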