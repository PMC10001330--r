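## Deep belief network classifier: greedy layer-wise RBM pretraining, then a
## softmax head fine-tuned together with the sigmoid layers by
## backpropagation on cross-entropy.

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass through the RBM stack
#'
#' Composes the hidden conditional means of the stacked RBMs:
#' `h^(1) = sigmoid(b^(1) + v' W^(1))`, `h^(l) = sigmoid(b^(l) + h^(l-1)' W^(l))`.
#'
#' @param model a [DBNModel-class].
#' @param X n x d input matrix (d = first RBM's visible dim).
#' @return list of layer activation matrices, one per RBM (last = top).
#' @export
dbnForward <- function(model, X) {
  acts <- vector("list", length(model@rbms))
  cur <- rbind(X)
  for (l in seq_along(model@rbms)) {
    cur <- hiddenActivation(model@rbms[[l]], cur)
    acts[[l]] <- cur
  }
  acts
}

## One fine-tune pass (minibatch SGD on cross-entropy) over the stack + head.
## Returns updated parameter list. Y is an n x K one-hot matrix.
fineTuneEpochs <- function(rbms, headW, headB, X, Y, lr, epochs, batchSize) {
  n <- nrow(X)
  L <- length(rbms)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batchSize)) {
      idx <- ord[s:min(s + batchSize - 1L, n)]
      xb <- X[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      m <- length(idx)
      # forward
      acts <- vector("list", L)
      cur <- xb
      for (l in seq_len(L)) {
        cur <- sigmoid(sweep(cur %*% rbms[[l]]@W, 2, rbms[[l]]@bHid, "+"))
        acts[[l]] <- cur
      }
      logits <- sweep(cur %*% headW, 2, headB, "+")
      p <- softmaxRows(logits)
      # backward
      dlog <- (p - yb) / m
      gHW <- crossprod(cur, dlog)
      gHB <- colSums(dlog)
      delta <- dlog %*% t(headW) * cur * (1 - cur)
      headW <- headW - lr * gHW
      headB <- headB - lr * gHB
      for (l in rev(seq_len(L))) {
        below <- if (l == 1L) xb else acts[[l - 1L]]
        gW <- crossprod(below, delta)
        gB <- colSums(delta)
        if (l > 1L) {
          delta <- delta %*% t(rbms[[l]]@W) * acts[[l - 1L]] * (1 - acts[[l - 1L]])
        }
        rbms[[l]]@W <- rbms[[l]]@W - lr * gW
        rbms[[l]]@bHid <- rbms[[l]]@bHid - lr * gB
      }
    }
  }
  list(rbms = rbms, headW = headW, headB = headB)
}

#' Train a DBN classifier
#'
#' Greedy layer-wise pretraining — the first RBM (gaussian visibles for
#' standardized real-valued features, bernoulli otherwise) on the inputs,
#' each further RBM on the previous layer's hidden probabilities — followed
#' by a softmax head warm-started on the frozen top activations and joint
#' backpropagation fine-tuning for `ftEpochs` epochs. With `ftEpochs = 0` the
#' DBN features stay frozen and only the head is trained. Deterministic per
#' seed.
#'
#' @param X n x d feature matrix (standardized when `visibleKind` is
#'   "gaussian", the default).
#' @param y length-n labels; must be a subset of `classes`.
#' @param hidden integer vector of hidden layer sizes.
#' @param cdK contrastive-divergence steps.
#' @param rbmLr,rbmEpochs pretraining learning rate / epochs.
#' @param ftLr,ftEpochs fine-tuning learning rate / epochs.
#' @param headEpochs warm-start epochs for the softmax head.
#' @param batchSize minibatch size.
#' @param seed integer seed.
#' @param classes class label set (defaults to the labels present).
#' @param visibleKind visible-unit type of the first RBM.
#' @return a [DBNModel-class].
#' @export
dbnTrain <- function(X, y, hidden = c(64L, 32L), cdK = 1L, rbmLr = 0.05,
                     rbmEpochs = 10L, ftLr = 0.1, ftEpochs = 30L,
                     headEpochs = 200L, batchSize = 32L, seed = 1L,
                     classes = sort(unique(y)),
                     visibleKind = c("gaussian", "bernoulli")) {
  visibleKind <- match.arg(visibleKind)
  X <- as.matrix(X)
  if (!all(y %in% classes))
    stop("label outside the class set: ",
         paste(setdiff(y, classes), collapse = ", "))
  K <- length(classes)
  # greedy pretraining
  rbms <- vector("list", length(hidden))
  cur <- X
  for (l in seq_along(hidden)) {
    rbms[[l]] <- trainRBMCD(cur, hidden[l], k = cdK, lr = rbmLr,
                            epochs = rbmEpochs, batchSize = batchSize,
                            visibleKind = if (l == 1L) visibleKind else "bernoulli",
                            seed = deriveSeed(seed, 20L + l))
    cur <- hiddenActivation(rbms[[l]], cur)
  }
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_len(nrow(X)), match(y, classes))] <- 1
  headW <- withLocalSeed(deriveSeed(seed, 40L),
                         matrix(rnorm(ncol(cur) * K, sd = 0.01), ncol(cur), K))
  headB <- rep(0, K)
  withLocalSeed(deriveSeed(seed, 41L), {
    # warm-start the head on frozen DBN features (plain softmax regression)
    for (ep in seq_len(headEpochs)) {
      logits <- sweep(cur %*% headW, 2, headB, "+")
      p <- softmaxRows(logits)
      dlog <- (p - Y) / nrow(X)
      headW <- headW - 1.0 * crossprod(cur, dlog)
      headB <- headB - 1.0 * colSums(dlog)
    }
    if (ftEpochs > 0L) {
      ft <- fineTuneEpochs(rbms, headW, headB, X, Y, ftLr, ftEpochs, batchSize)
      rbms <- ft$rbms; headW <- ft$headW; headB <- ft$headB
    }
  })
  new("DBNModel", rbms = rbms, headW = headW, headB = headB,
      classes = as.character(classes),
      fineTune = list(lr = ftLr, epochs = ftEpochs, headEpochs = headEpochs))
}

#' @describeIn dbnTrain cross-entropy of the model on labeled data (nats per
#'   sample), used to monitor fine-tuning.
#' @param model a [DBNModel-class].
#' @export
dbnCrossEntropy <- function(model, X, y) {
  p <- predict(model, X)$probabilities
  idx <- cbind(seq_len(nrow(p)), match(y, model@classes))
  -mean(log(pmax(p[idx], 1e-300)))
}

#' @importFrom stats predict
setGeneric("predict")

#' Predict class probabilities and labels
#'
#' Softmax probabilities over the classes (rows sum to 1) and their argmax
#' labels.
#'
#' @param object a [DBNModel-class].
#' @param newdata n x d feature matrix.
#' @return list with `probabilities` (n x K matrix, columns named by class)
#'   and `labels` (character vector).
#' @export
setMethod("predict", "DBNModel", function(object, newdata) {
  acts <- dbnForward(object, as.matrix(newdata))
  top <- acts[[length(acts)]]
  p <- softmaxRows(sweep(top %*% object@headW, 2, object@headB, "+"))
  colnames(p) <- object@classes
  list(probabilities = p,
       labels = object@classes[max.col(p, ties.method = "first")])
})
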