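# Shared fixtures and independent oracles used across test files.

# Brute-force clipped-histogram / CDF mapping for a single-block grayscale
# image: independent of the package's CLAHE internals (direct arithmetic on
# the pixel vector).
bruteClaheSingleBlock <- function(mat, clipLimit, nBins) {
  vals <- as.vector(mat)
  n <- length(vals)
  bin <- pmin(nBins, floor(vals / 256 * nBins) + 1)
  counts <- numeric(nBins)
  for (b in bin) counts[b] <- counts[b] + 1
  if (is.finite(clipLimit)) {
    ceilCount <- clipLimit * n / nBins
    excess <- 0
    for (i in seq_len(nBins)) {
      if (counts[i] > ceilCount) {
        excess <- excess + counts[i] - ceilCount
        counts[i] <- ceilCount
      }
    }
    counts <- counts + excess / nBins
  }
  cdf <- cumsum(counts)
  cdfMin <- cdf[which(cdf > 0)[1]]
  mapped <- (cdf[bin] - cdfMin) / (n - cdfMin) * 255
  matrix(mapped, nrow(mat), ncol(mat))
}

# Naive nested-loop depthwise-separable convolution ("same" zero padding,
# ReLU after each stage), used as the oracle for dsConvBlock.
naiveDsConv <- function(x, params, stride) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(params$dw)[1]; half <- (k - 1) %/% 2
  ri <- seq(1, h, by = stride); ci <- seq(1, w, by = stride)
  dw <- array(0, dim = c(length(ri), length(ci), cin))
  for (c in seq_len(cin)) {
    for (oi in seq_along(ri)) {
      for (oj in seq_along(ci)) {
        acc <- 0
        for (di in seq_len(k)) {
          for (dj in seq_len(k)) {
            ii <- ri[oi] + di - 1 - half
            jj <- ci[oj] + dj - 1 - half
            if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
              acc <- acc + params$dw[di, dj, c] * x[ii, jj, c]
          }
        }
        dw[oi, oj, c] <- max(acc + params$dwBias[c], 0)
      }
    }
  }
  cout <- ncol(params$pw)
  out <- array(0, dim = c(length(ri), length(ci), cout))
  for (co in seq_len(cout)) {
    for (oi in seq_along(ri)) {
      for (oj in seq_along(ci)) {
        acc <- params$pwBias[co]
        for (c in seq_len(cin)) acc <- acc + dw[oi, oj, c] * params$pw[c, co]
        out[oi, oj, co] <- max(acc, 0)
      }
    }
  }
  out
}

# Hand trapezoidal one-vs-rest ROC AUC, independent of pROC.
handAUC <- function(response, score) {
  ord <- order(score, decreasing = TRUE)
  resp <- response[ord]
  nPos <- sum(resp); nNeg <- sum(!resp)
  # accumulate over distinct thresholds to handle ties correctly
  sc <- score[ord]
  tpr <- c(0); fpr <- c(0); tp <- 0; fp <- 0
  i <- 1
  while (i <= length(sc)) {
    j <- i
    while (j <= length(sc) && sc[j] == sc[i]) j <- j + 1
    tp <- tp + sum(resp[i:(j - 1)])
    fp <- fp + sum(!resp[i:(j - 1)])
    tpr <- c(tpr, tp / nPos); fpr <- c(fpr, fp / nNeg)
    i <- j
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Small separable 5-class Gaussian blob set for classifier tests.
makeBlobs <- function(nPerClass = 100, sd = 0.4, seed = 11) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 2, 8), 5, 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:5, function(k)
    sweep(matrix(rnorm(nPerClass * 2, sd = sd), nPerClass, 2), 2,
          centers[k, ], "+")))
  list(X = scale(X), y = rep(paste0("class", 1:5), each = nPerClass))
}

# Gibbs sample binary data from a planted small RBM.
samplePlantedRBM <- function(planted, n = 200, burn = 500, seed = 31) {
  set.seed(seed)
  nVis <- nrow(planted@W); nHid <- ncol(planted@W)
  v <- matrix(as.numeric(runif(nVis) < 0.5), 1, nVis)
  out <- matrix(0, n, nVis)
  for (i in seq_len(burn + n)) {
    h <- hiddenActivation(planted, v)
    hs <- matrix(as.numeric(runif(nHid) < h), 1, nHid)
    pv <- visibleActivation(planted, hs)
    v <- matrix(as.numeric(runif(nVis) < pv), 1, nVis)
    if (i > burn) out[i - burn, ] <- v
  }
  out
}
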