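## Depthwise-separable convolutional feature extraction.
##
## A small MobileNet-style stack: each block applies a k x k depthwise
## convolution per input channel ("same" zero padding), then a 1 x 1
## pointwise convolution mixing channels, each followed by ReLU. Global
## average pooling over the final feature map yields the feature vector.

relu <- function(x) pmax(x, 0)

#' Parameter counts of a depthwise-separable vs standard convolution
#'
#' Illustrates the factorization saving: a depthwise-separable block costs
#' `k^2 * cin + cin * cout` weights where a standard convolution costs
#' `k^2 * cin * cout`.
#'
#' @param k kernel size, `cin`/`cout` channel counts.
#' @param cin,cout input/output channels.
#' @return named numeric vector with `separable` and `standard` counts.
#' @export
dsParamCount <- function(k, cin, cout) {
  c(separable = k * k * cin + cin * cout, standard = k * k * cin * cout)
}

## Depthwise k x k convolution of one channel plane (matrix), "same" zero
## padding, given a k x k kernel. stride applied afterwards by the caller.
depthwiseChannel <- function(plane, kern) {
  k <- nrow(kern)
  half <- (k - 1L) %/% 2L
  h <- nrow(plane); w <- ncol(plane)
  padded <- matrix(0, h + 2L * half, w + 2L * half)
  padded[(half + 1L):(half + h), (half + 1L):(half + w)] <- plane
  out <- matrix(0, h, w)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      out <- out + kern[di, dj] *
        padded[(di):(di + h - 1L), (dj):(dj + w - 1L)]
    }
  }
  out
}

#' One depthwise-separable convolution block
#'
#' Depthwise k x k convolution per input channel (+ bias, ReLU), then a
#' pointwise 1 x 1 convolution mixing channels (+ bias, ReLU). "Same"
#' zero padding; stride subsamples the depthwise output.
#'
#' @param x H x W x C_in array.
#' @param params list with `dw` (k x k x C_in depthwise kernels), `dwBias`
#'   (length C_in), `pw` (C_in x C_out pointwise weights), `pwBias`
#'   (length C_out).
#' @param stride 1 or 2.
#' @return H' x W' x C_out array with H' = ceiling(H / stride).
#' @export
dsConvBlock <- function(x, params, stride = 1L) {
  stopifnot(stride %in% c(1L, 2L))
  cin <- dim(x)[3]
  if (dim(params$dw)[3] != cin || nrow(params$pw) != cin)
    stop("channel mismatch: input has ", cin, " channels, params expect ",
         dim(params$dw)[3])
  h <- dim(x)[1]; w <- dim(x)[2]
  ri <- seq(1L, h, by = stride); ci <- seq(1L, w, by = stride)
  dwOut <- array(0, dim = c(length(ri), length(ci), cin))
  for (c in seq_len(cin)) {
    plane <- matrix(x[, , c], h, w)
    kern <- matrix(params$dw[, , c], dim(params$dw)[1], dim(params$dw)[2])
    conv <- depthwiseChannel(plane, kern) + params$dwBias[c]
    dwOut[, , c] <- relu(conv[ri, ci, drop = FALSE])
  }
  hp <- length(ri); wp <- length(ci)
  flat <- matrix(dwOut, hp * wp, cin)
  mixed <- flat %*% params$pw +
    matrix(params$pwBias, hp * wp, ncol(params$pw), byrow = TRUE)
  array(relu(mixed), dim = c(hp, wp, ncol(params$pw)))
}

## He-style random initialization of all block parameters, deterministic in
## the seed.
initExtractorWeights <- function(cfg) {
  withLocalSeed(cfg@weightsSeed, {
    nb <- length(cfg@channels) - 1L
    lapply(seq_len(nb), function(b) {
      cin <- cfg@channels[b]; cout <- cfg@channels[b + 1L]
      k <- cfg@kernel
      list(
        dw = array(rnorm(k * k * cin, sd = sqrt(2 / (k * k))), dim = c(k, k, cin)),
        dwBias = rep(0, cin),
        pw = matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout),
        pwBias = rep(0, cout)
      )
    })
  })
}

## Forward pass through all blocks; returns list(map = final H x W x C array,
## feature = GAP vector).
extractorForward <- function(px01, cfg, weights) {
  x <- px01
  for (b in seq_along(weights)) {
    x <- dsConvBlock(x, weights[[b]], stride = cfg@strides[b])
  }
  list(map = x, feature = apply(x, 3, mean))
}

## Resize a tile's pixels to cfg@inputSize via bilinear interpolation and
## rescale to [0, 1]. EBImage uses width-first layout, hence the aperm pair.
resizeTile <- function(px, inputSize) {
  if (all(dim(px)[1:2] == inputSize)) return(px / 255)
  img <- EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
  r <- EBImage::resize(img, w = inputSize[2], h = inputSize[1])
  aperm(EBImage::imageData(r), c(2, 1, 3))
}

#' Extract a feature matrix from tiles
#'
#' Resizes every tile to `cfg@inputSize`, runs the depthwise-separable stack,
#' and global-average-pools the last feature map into a `featureDim(cfg)`
#' vector. With `weightsMode = "random_fixed"` (default) the weights are a
#' fixed-seed random draw, making the map a deterministic function of the
#' pixels. With `weightsMode = "trained"` the final block's pointwise weights
#' are first recalibrated on the rows in `trainRows` via a temporary softmax
#' head (discarded afterwards).
#'
#' @param tiles list of [ImageTile-class] (non-empty).
#' @param cfg an [ExtractorConfig-class].
#' @param trainRows row indices used by the `trained` mode (ignored
#'   otherwise); defaults to all labeled tiles.
#' @return a [FeatureMatrix-class] (unstandardized).
#' @export
extractFeatures <- function(tiles, cfg = extractorConfig(), trainRows = NULL) {
  if (length(tiles) == 0L) stop("tiles must be non-empty")
  for (t in tiles) if (dim(t@pixels)[3] != 3L) stop("non-RGB input tile")
  if (cfg@channels[1] != 3L) stop("extractor input channels must be 3 (RGB)")
  weights <- initExtractorWeights(cfg)
  inputs <- lapply(tiles, function(t) resizeTile(t@pixels, cfg@inputSize))

  if (cfg@weightsMode == "trained") {
    labels <- tileLabels(tiles)
    if (is.null(trainRows)) trainRows <- which(!is.na(labels))
    if (length(trainRows) == 0L) stop("'trained' mode needs labeled trainRows")
    weights <- tuneLastPointwise(inputs[trainRows], labels[trainRows], cfg,
                                 weights)
  }

  vals <- t(vapply(inputs, function(x)
    extractorForward(x, cfg, weights)$feature, numeric(featureDim(cfg))))
  new("FeatureMatrix", values = vals, labels = tileLabels(tiles),
      ids = vapply(tiles, function(t) t@sourceId, character(1)))
}

## Supervised recalibration of the last block's pointwise layer: gradient
## descent on a softmax head through GAP and the final ReLU; the head is
## discarded. Exact gradients; everything before the last pointwise layer is
## frozen.
tuneLastPointwise <- function(inputs, labels, cfg, weights, epochs = 20L,
                              lr = 0.05) {
  nb <- length(weights)
  classes <- sort(unique(labels))
  K <- length(classes)
  y <- match(labels, classes)
  # cache depthwise output of the last block for every input
  pre <- lapply(inputs, function(x) {
    for (b in seq_len(nb - 1L)) x <- dsConvBlock(x, weights[[b]], cfg@strides[b])
    # depthwise part of the final block
    cin <- dim(x)[3]
    h <- dim(x)[1]; w <- dim(x)[2]
    ri <- seq(1L, h, by = cfg@strides[nb]); ci <- seq(1L, w, by = cfg@strides[nb])
    dwOut <- array(0, dim = c(length(ri), length(ci), cin))
    for (c in seq_len(cin)) {
      conv <- depthwiseChannel(x[, , c], weights[[nb]]$dw[, , c]) +
        weights[[nb]]$dwBias[c]
      dwOut[, , c] <- relu(conv[ri, ci, drop = FALSE])
    }
    matrix(dwOut, prod(dim(dwOut)[1:2]), cin)   # positions x cin
  })
  pw <- weights[[nb]]$pw; pwB <- weights[[nb]]$pwBias
  cout <- ncol(pw)
  hw <- withLocalSeed(deriveSeed(cfg@weightsSeed, 7L),
                      matrix(rnorm(cout * K, sd = 0.1), cout, K))
  hb <- rep(0, K)
  n <- length(inputs)
  for (ep in seq_len(epochs)) {
    for (i in seq_len(n)) {
      z <- pre[[i]]                       # P x cin
      act <- z %*% pw + matrix(pwB, nrow(z), cout, byrow = TRUE)
      a <- relu(act)
      f <- colMeans(a)                    # GAP feature
      logits <- drop(f %*% hw) + hb
      pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
      dlog <- pr; dlog[y[i]] <- dlog[y[i]] - 1
      # head gradients
      gHw <- outer(f, dlog); gHb <- dlog
      # back through GAP and ReLU into pointwise weights
      df <- drop(hw %*% dlog)             # cout
      da <- matrix(df / nrow(z), nrow(z), cout, byrow = TRUE) * (act > 0)
      gPw <- crossprod(z, da); gPb <- colSums(da)
      pw <- pw - lr * gPw; pwB <- pwB - lr * gPb
      hw <- hw - lr * gHw; hb <- hb - lr * gHb
    }
  }
  weights[[nb]]$pw <- pw
  weights[[nb]]$pwBias <- pwB
  weights
}

#' Standardize features using statistics of a training subset
#'
#' Per-feature z-scoring with mean and standard deviation computed on
#' `fitRows` only; all rows (training and held-out) are transformed with the
#' training statistics. Zero-variance features map to 0.
#'
#' @param fm a [FeatureMatrix-class].
#' @param fitRows non-empty integer row indices to fit on.
#' @return a standardized [FeatureMatrix-class].
#' @export
standardizeFeatures <- function(fm, fitRows = seq_len(nrow(fm@values))) {
  if (length(fitRows) == 0L) stop("fitRows must be non-empty")
  v <- fm@values
  ctr <- colMeans(v[fitRows, , drop = FALSE])
  scl <- apply(v[fitRows, , drop = FALSE], 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- Inf   # zero-variance features -> 0
  z <- sweep(sweep(v, 2, ctr, "-"), 2, scl, "/")
  new("FeatureMatrix", values = z, labels = fm@labels, ids = fm@ids,
      center = ctr, scale = ifelse(is.infinite(scl), 0, scl),
      fitRows = as.integer(fitRows))
}
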