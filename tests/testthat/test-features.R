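test_that("parameter counts show the depthwise-separable factorization saving", {
  counts <- dsParamCount(3, 16, 32)
  expect_equal(unname(counts["separable"]), 3 * 3 * 16 + 16 * 32)  # 656
  expect_equal(unname(counts["standard"]), 3 * 3 * 16 * 32)        # 4608
})

test_that("dsConvBlock matches a naive nested-loop convolution oracle", {
  set.seed(41)
  for (trial in 1:5) {
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    cin <- sample(1:3, 1); cout <- sample(1:4, 1)
    x <- array(rnorm(h * w * cin), dim = c(h, w, cin))
    params <- list(dw = array(rnorm(9 * cin), dim = c(3, 3, cin)),
                   dwBias = rnorm(cin),
                   pw = matrix(rnorm(cin * cout), cin, cout),
                   pwBias = rnorm(cout))
    for (stride in c(1L, 2L)) {
      expect_equal(dsConvBlock(x, params, stride),
                   naiveDsConv(x, params, stride), tolerance = 1e-6)
    }
  }
})

test_that("zero weights give zero output and channel mismatches error", {
  x <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  params <- list(dw = array(0, dim = c(3, 3, 2)), dwBias = c(0, 0),
                 pw = matrix(0, 2, 3), pwBias = rep(0, 3))
  expect_equal(as.vector(dsConvBlock(x, params, 1L)), rep(0, 48))
  bad <- params; bad$dw <- array(0, dim = c(3, 3, 5))
  expect_error(dsConvBlock(x, bad, 1L), "channel mismatch")
})

test_that("1x1 input with identity-like pointwise equals the depthwise response", {
  x <- array(c(0.5, -0.2), dim = c(1, 1, 2))
  params <- list(dw = array(c(rep(0, 4), 2, rep(0, 4),     # center tap only
                              rep(0, 4), 3, rep(0, 4)), dim = c(3, 3, 2)),
                 dwBias = c(0.1, 0),
                 pw = diag(2), pwBias = c(0, 0))
  out <- dsConvBlock(x, params, 1L)
  # depthwise: relu(2*0.5 + 0.1) = 1.1 ; relu(3*-0.2) = 0 ; pointwise identity
  expect_equal(as.vector(out), c(1.1, 0))
})

test_that("feature extraction is deterministic and shaped n x featureDim", {
  tiles <- generateTiles(3, size = 32, seed = 2)
  cfg <- extractorConfig(inputSize = c(32L, 32L), weightsSeed = 99L)
  fm1 <- extractFeatures(tiles, cfg)
  fm2 <- extractFeatures(tiles, cfg)
  expect_identical(featureValues(fm1), featureValues(fm2))
  expect_equal(dim(featureValues(fm1)), c(15L, featureDim(cfg)))
  # same tile twice -> identical rows
  fm3 <- extractFeatures(list(tiles[[1]], tiles[[1]]), cfg)
  expect_identical(featureValues(fm3)[1, ], featureValues(fm3)[2, ])
})

test_that("classes with disjoint mean colors separate in feature space", {
  rec <- defaultTileRecipes()[c(2, 5), ]   # brightest vs darkest palette
  tiles <- generateTiles(10, size = 32, recipes = rec, seed = 3)
  labels <- tileLabels(tiles)
  fm <- extractFeatures(tiles, extractorConfig(inputSize = c(32L, 32L)))
  X <- featureValues(fm)
  c1 <- colMeans(X[labels == rec$class[1], ])
  c2 <- colMeans(X[labels == rec$class[2], ])
  between <- sqrt(sum((c1 - c2)^2))
  within <- mean(vapply(seq_len(nrow(X)), function(i) {
    ctr <- if (labels[i] == rec$class[1]) c1 else c2
    sqrt(sum((X[i, ] - ctr)^2))
  }, numeric(1)))
  expect_gt(between, within)
})

test_that("global average pooling is invariant to spatial permutation", {
  set.seed(44)
  map <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8))
  gap <- apply(map, 3, mean)
  perm <- sample(16)
  shuffled <- array(apply(map, 3, function(pl) as.vector(pl)[perm]),
                    dim = dim(map))
  expect_equal(apply(shuffled, 3, mean), gap, tolerance = 1e-12)
})

test_that("standardization uses training-row statistics only", {
  fm <- new("FeatureMatrix",
            values = matrix(c(1, 2, 3, 10, 0, 1, 4, 8), 4, 2),
            labels = rep(NA_character_, 4), ids = as.character(1:4))
  fs <- standardizeFeatures(fm, fitRows = 1:2)
  v <- featureValues(fm)
  ctr <- colMeans(v[1:2, ]); scl <- apply(v[1:2, ], 2, sd)
  expect_equal(featureValues(fs), sweep(sweep(v, 2, ctr), 2, scl, "/"))
  # fitting on all rows gives zero column means
  fsAll <- standardizeFeatures(fm)
  expect_lt(max(abs(colMeans(featureValues(fsAll)))), 1e-9)
  # constant column maps to zeros without error
  fmC <- new("FeatureMatrix", values = cbind(c(1, 1, 1), c(1, 2, 3)),
             labels = rep(NA_character_, 3), ids = as.character(1:3))
  expect_equal(featureValues(standardizeFeatures(fmC))[, 1], rep(0, 3))
})

test_that("trained weights mode refines features deterministically", {
  tiles <- generateTiles(4, size = 32, seed = 6)
  cfg <- extractorConfig(inputSize = c(32L, 32L), channels = c(3L, 8L, 16L),
                         strides = c(2L, 2L), weightsMode = "trained")
  fm1 <- extractFeatures(tiles, cfg)
  fm2 <- extractFeatures(tiles, cfg)
  expect_identical(featureValues(fm1), featureValues(fm2))
  expect_true(all(is.finite(featureValues(fm1))))
  expect_equal(ncol(featureValues(fm1)), 16L)
})
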