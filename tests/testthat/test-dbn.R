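test_that("stacked forward pass equals composed RBM conditional means", {
  blobs <- makeBlobs(nPerClass = 20, seed = 61)
  model <- dbnTrain(blobs$X, blobs$y, hidden = c(8, 6), cdK = 1, rbmLr = 0.05,
                    rbmEpochs = 3, ftLr = 0.1, ftEpochs = 2, seed = 5)
  acts <- dbnForward(model, blobs$X)
  manual <- hiddenActivation(model@rbms[[2]],
                             hiddenActivation(model@rbms[[1]], blobs$X))
  expect_equal(acts[[2]], manual, tolerance = 1e-9)
})

test_that("zero fine-tune epochs still yields a working head-only model", {
  blobs <- makeBlobs(nPerClass = 20, seed = 62)
  model <- dbnTrain(blobs$X, blobs$y, hidden = c(8, 6), cdK = 1,
                    rbmEpochs = 3, ftEpochs = 0, seed = 5)
  expect_s4_class(model, "DBNModel")
  pr <- predict(model, blobs$X)
  expect_equal(rowSums(pr$probabilities), rep(1, 100), tolerance = 1e-9)
  expect_true(all(pr$labels %in% unique(blobs$y)))
})

test_that("fine-tuned DBN separates 5-class synthetic blobs", {
  blobs <- makeBlobs(nPerClass = 100, seed = 63)
  model <- dbnTrain(blobs$X, blobs$y, hidden = c(16, 8), cdK = 1,
                    rbmLr = 0.05, rbmEpochs = 10, ftLr = 0.5, ftEpochs = 100,
                    seed = 7)
  pr <- predict(model, blobs$X)
  expect_gte(mean(pr$labels == blobs$y), 0.95)
})

test_that("prediction probabilities are proper and deterministic", {
  blobs <- makeBlobs(nPerClass = 15, seed = 64)
  model <- dbnTrain(blobs$X, blobs$y, hidden = c(8, 6), cdK = 1,
                    rbmEpochs = 2, ftEpochs = 2, seed = 3)
  X <- rbind(blobs$X[1, ], blobs$X[1, ], blobs$X[2, ])
  pr <- predict(model, X)
  expect_equal(rowSums(pr$probabilities), rep(1, 3), tolerance = 1e-9)
  expect_identical(pr$probabilities[1, ], pr$probabilities[2, ])
  expect_equal(pr$labels,
               model@classes[apply(pr$probabilities, 1, which.max)])
  expect_error(predict(model, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("a gentle fine-tune epoch does not degrade training cross-entropy", {
  blobs <- makeBlobs(nPerClass = 30, seed = 65)
  frozen <- dbnTrain(blobs$X, blobs$y, hidden = c(8, 6), cdK = 1,
                     rbmEpochs = 3, ftEpochs = 0, seed = 9)
  tuned <- dbnTrain(blobs$X, blobs$y, hidden = c(8, 6), cdK = 1,
                    rbmEpochs = 3, ftLr = 1e-3, ftEpochs = 1, seed = 9)
  ce0 <- dbnCrossEntropy(frozen, blobs$X, blobs$y)
  ce1 <- dbnCrossEntropy(tuned, blobs$X, blobs$y)
  expect_lt(ce1, ce0 + 1e-3)
})

test_that("DBN training rejects labels outside the class set and is seeded", {
  blobs <- makeBlobs(nPerClass = 10, seed = 66)
  expect_error(dbnTrain(blobs$X, blobs$y, classes = c("class1", "class2"),
                        hidden = c(4, 4), rbmEpochs = 1, ftEpochs = 1),
               "label outside")
  a <- dbnTrain(blobs$X, blobs$y, hidden = c(6, 4), rbmEpochs = 2,
                ftEpochs = 3, seed = 12)
  b <- dbnTrain(blobs$X, blobs$y, hidden = c(6, 4), rbmEpochs = 2,
                ftEpochs = 3, seed = 12)
  expect_identical(a@headW, b@headW)
  expect_identical(a@rbms[[1]]@W, b@rbms[[1]]@W)
})

test_that("autoencoder reconstruction loss and encoding behave as specified", {
  set.seed(67)
  X <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(aeLoss(X, X), 0)                     # perfect reconstruction
  delta <- matrix(1, 50, 6)
  expect_equal(aeLoss(X + delta, X), sum(delta^2) / 50)
  # rank-2 data: training reduces the loss from initialization
  Z <- matrix(rnorm(200 * 2), 200, 2) %*% matrix(rnorm(2 * 10), 2, 10)
  ae0 <- trainAutoencoder(Z, c(10, 6, 2), epochs = 0, seed = 4)
  ae1 <- trainAutoencoder(Z, c(10, 6, 2), epochs = 80, lr = 0.02, seed = 4)
  l0 <- aeLoss(aeReconstruct(ae0, Z), Z)
  l1 <- aeLoss(aeReconstruct(ae1, Z), Z)
  expect_lt(l1, l0)
  # encode output dimension equals the bottleneck
  expect_equal(dim(aeEncode(ae1, Z)), c(200L, 2L))
  # deterministic per seed
  ae2 <- trainAutoencoder(Z, c(10, 6, 2), epochs = 80, lr = 0.02, seed = 4)
  expect_identical(aeReconstruct(ae1, Z), aeReconstruct(ae2, Z))
})
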