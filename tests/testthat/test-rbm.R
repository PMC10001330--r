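test_that("sigmoid is correct, symmetric, and overflow-safe", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(1, 10, 100)) expect_equal(sigmoid(-x), 1 - sigmoid(x))
  expect_equal(sigmoid(-1000), 0)
  expect_equal(sigmoid(1000), 1)
  expect_false(any(is.nan(sigmoid(c(-1e6, 1e6)))))
})

test_that("conditional activations match direct matrix arithmetic", {
  W <- matrix(c(0.5, -1, 2, 0.3, 1, -0.7), 3, 2)
  m <- new("RBM", W = W, bVis = c(0.1, -0.2, 0.3), bHid = c(0.4, -0.5),
           visibleKind = "bernoulli", beta = rep(1, 3))
  v <- c(1, 0, 1)
  expect_equal(as.vector(hiddenActivation(m, v)),
               sigmoid(c(0.4, -0.5) + as.vector(t(W) %*% v)))
  h <- c(1, 0)
  expect_equal(as.vector(visibleActivation(m, h)),
               sigmoid(c(0.1, -0.2, 0.3) + as.vector(W %*% h)))
  # zero weights reduce to the biases
  m0 <- new("RBM", W = matrix(0, 3, 2), bVis = c(0.1, -0.2, 0.3),
            bHid = c(0, 0), visibleKind = "bernoulli", beta = rep(1, 3))
  expect_equal(as.vector(hiddenActivation(m0, v)), c(0.5, 0.5))
  expect_equal(as.vector(visibleActivation(m0, h)),
               sigmoid(c(0.1, -0.2, 0.3)))
  # gaussian visibles return the conditional mean exactly
  mg <- new("RBM", W = W, bVis = c(1, 2, 3), bHid = c(0, 0),
            visibleKind = "gaussian", beta = rep(1, 3))
  expect_equal(as.vector(visibleActivation(mg, c(0, 0))), c(1, 2, 3))
  expect_error(hiddenActivation(m, c(1, 0)), "dimension mismatch")
  expect_error(visibleActivation(m, c(1, 0, 1)), "dimension mismatch")
  # activations stay strictly inside (0, 1) for finite inputs
  act <- hiddenActivation(m, matrix(rnorm(30), 10, 3))
  expect_true(all(act > 0 & act < 1))
})

test_that("unnormalized visible probabilities match exhaustive energy enumeration", {
  set.seed(51)
  m <- new("RBM", W = matrix(rnorm(12, sd = 1.5), 4, 3), bVis = rnorm(4),
           bHid = rnorm(3), visibleKind = "bernoulli", beta = rep(1, 4))
  allH <- as.matrix(expand.grid(rep(list(c(0, 1)), 3)))
  allV <- as.matrix(expand.grid(rep(list(c(0, 1)), 4)))
  for (i in seq_len(nrow(allV))) {
    v <- allV[i, ]
    # independent oracle: explicit energy sum over all 8 hidden states
    pStar <- sum(apply(allH, 1, function(h)
      exp(sum(m@bVis * v) + sum(m@bHid * h) + drop(v %*% m@W %*% h))))
    expect_equal(rbmUnnormalizedProb(m, v), pStar, tolerance = 1e-8)
  }
  # the energy function itself agrees with the hand formula
  v <- allV[7, ]; h <- allH[3, ]
  expect_equal(rbmEnergy(m, v, h),
               -sum(m@bVis * v) - sum(m@bHid * h) - drop(v %*% m@W %*% h))
})

test_that("zero learning rate leaves parameters unchanged and k < 1 errors", {
  set.seed(52)
  data <- matrix(as.numeric(runif(80) < 0.5), 20, 4)
  m0 <- rbm(4, 3, "bernoulli", seed = 8)
  m1 <- trainRBMCD(data, 3, k = 1, lr = 0, epochs = 5, seed = 8, init = m0)
  expect_identical(m1@W, m0@W)
  expect_identical(m1@bVis, m0@bVis)
  expect_error(trainRBMCD(data, 3, k = 0), "k must be >= 1")
})

test_that("CD training increases exact log-likelihood on planted-model data", {
  set.seed(53)
  planted <- new("RBM", W = matrix(rnorm(12, sd = 2), 4, 3), bVis = rnorm(4),
                 bHid = rnorm(3), visibleKind = "bernoulli", beta = rep(1, 4))
  data <- samplePlantedRBM(planted, n = 200)
  init <- rbm(4, 3, "bernoulli", seed = 9)
  ll0 <- rbmExactLogLik(init, data)
  trained <- trainRBMCD(data, 3, k = 1, lr = 0.1, epochs = 50, seed = 9,
                        init = init)
  ll50 <- rbmExactLogLik(trained, data)
  expect_gt(ll50, ll0)
})

test_that("reconstruction error decreases over training (moving average)", {
  set.seed(54)
  # two binary prototypes + flip noise
  proto <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  data <- proto[sample(1:2, 100, replace = TRUE), ]
  flip <- matrix(runif(600) < 0.05, 100, 6)
  data[flip] <- 1 - data[flip]
  recon <- function(m) {
    h <- hiddenActivation(m, data)
    mean((visibleActivation(m, h) - data)^2)
  }
  m <- rbm(6, 4, "bernoulli", seed = 10)
  errs <- numeric(6)
  errs[1] <- recon(m)
  for (i in 2:6) {
    m <- trainRBMCD(data, 4, k = 1, lr = 0.1, epochs = 5, seed = 10 + i,
                    init = m)
    errs[i] <- recon(m)
  }
  expect_lt(mean(errs[4:6]), mean(errs[1:2]))
})

test_that("training is reproducible per seed", {
  set.seed(55)
  data <- matrix(as.numeric(runif(120) < 0.4), 30, 4)
  a <- trainRBMCD(data, 3, k = 2, lr = 0.05, epochs = 8, seed = 77)
  b <- trainRBMCD(data, 3, k = 2, lr = 0.05, epochs = 8, seed = 77)
  expect_identical(a@W, b@W)
  c <- trainRBMCD(data, 3, k = 2, lr = 0.05, epochs = 8, seed = 78)
  expect_false(identical(a@W, c@W))
})
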