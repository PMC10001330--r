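wideSpace <- function(d = 1) searchSpace(rep(-100, d), rep(100, d))
pin <- function(n, d, v) matrix(v, n, d)

test_that("adaptive step scale CF has the right endpoints and is non-increasing", {
  expect_equal(computeCF(0, 100), 1.0)
  expect_equal(computeCF(100, 100), 0.0)
  expect_equal(computeCF(50, 100), 0.5)   # (1 - 0.5)^1
  cf <- vapply(0:200, computeCF, numeric(1), iMax = 200)
  expect_true(all(diff(cf) <= 1e-12))
  expect_error(computeCF(101, 100), "0 <= i <= iMax")
})

test_that("population initialization is uniform in bounds and seeded", {
  space <- searchSpace(c(-2, 0, 10), c(3, 1, 20))
  cfg <- mpaConfig(n = 40, seed = 5)
  p1 <- initPopulation(space, cfg)
  p2 <- initPopulation(space, cfg)
  expect_identical(p1, p2)
  # exhaustive containment over many draws
  big <- initPopulation(space, mpaConfig(n = 4000, seed = 6))
  expect_true(all(sweep(big, 2, space@lb, ">=") & sweep(big, 2, space@ub, "<=")))
  # degenerate bounds: positions collapse onto lb as ub -> lb
  eps <- 1e-12
  tiny <- initPopulation(searchSpace(c(1, 1), c(1 + eps, 1 + eps)),
                         mpaConfig(n = 10, seed = 7))
  expect_equal(as.vector(tiny), rep(1, 20), tolerance = 1e-10)
})

test_that("Levy draws are reproducible, shaped, and heavy-tailed with index alpha", {
  set.seed(1); a <- levyVector(100, 1.5)
  set.seed(1); b <- levyVector(100, 1.5)
  expect_identical(a, b)
  expect_length(levyVector(17, 1.8), 17)
  # Hill tail-index estimate on the top 1% of 1e5 absolute draws
  set.seed(2)
  x <- abs(levyVector(1e5, 1.5))
  top <- sort(x, decreasing = TRUE)[1:1000]
  hill <- 1 / mean(log(top / top[1000]))
  expect_lt(abs(hill - 1.5), 0.3)
})

test_that("phase 1 matches hand arithmetic and its fixed points", {
  cfg <- mpaConfig(n = 1, p = 0.5, seed = 1)
  # Step = RB(Elite - RB Prey); Prey + P R Step = 1 + 0.5*1*0.75 = 1.375
  out <- phase1Update(pin(1, 1, 1), 2, list(RB = pin(1, 1, 0.5), R = pin(1, 1, 1)),
                      cfg, wideSpace())
  expect_equal(as.vector(out), 1.375)
  # RB = 0 -> zero step
  out0 <- phase1Update(pin(1, 1, 1), 2, list(RB = pin(1, 1, 0), R = pin(1, 1, 1)),
                       cfg, wideSpace())
  expect_equal(as.vector(out0), 1)
  # RB = 1 and Elite = Prey -> fixed point
  outF <- phase1Update(pin(1, 1, 2), 2, list(RB = pin(1, 1, 1), R = pin(1, 1, 1)),
                       cfg, wideSpace())
  expect_equal(as.vector(outF), 2)
})

test_that("phase 2 halves follow their worked equations", {
  cfg <- mpaConfig(n = 2, p = 0.5, seed = 1)
  ctx <- list(RB = pin(2, 1, 0.5), RL = pin(2, 1, 0.5), R = pin(2, 1, 0.5))
  out <- phase2Update(matrix(c(1, 3), 2, 1), 2, ctx, cfg, wideSpace(), cf = 0.5)
  # agent 1 (Levy half): 1 + 0.5*0.5*[0.5*(2 - 0.5*1)] = 1.1875
  expect_equal(out[1, 1], 1.1875)
  # agent 2 (Brownian half): 2 + 0.5*0.5*[0.5*2 - 0.5*3] = 1.875
  expect_equal(out[2, 1], 1.875)
  # RL = 0 leaves the first half unchanged
  ctx0 <- list(RB = pin(2, 1, 0.5), RL = pin(2, 1, 0), R = pin(2, 1, 0.5))
  out0 <- phase2Update(matrix(c(1, 3), 2, 1), 2, ctx0, cfg, wideSpace(), cf = 0.5)
  expect_equal(out0[1, 1], 1)
  # CF = 0 collapses the second half onto the elite
  outC <- phase2Update(matrix(c(1, 3), 2, 1), 2, ctx, cfg, wideSpace(), cf = 0)
  expect_equal(outC[2, 1], 2)
})

test_that("phase 3 matches hand arithmetic in both rule variants", {
  ctx <- list(RL = pin(1, 1, 0.5))
  # default (inner Levy factor): 2 + 0.5*0.25*[0.5*(0.5*2 - 3)] = 1.875
  out <- phase3Update(pin(1, 1, 3), 2, ctx, mpaConfig(n = 1, seed = 1),
                      wideSpace(), cf = 0.25)
  expect_equal(as.vector(out), 1.875)
  # literal printed form: 2 + 0.5*0.25*[0.5*(2 - 3)] = 1.9375
  outL <- phase3Update(pin(1, 1, 3), 2, ctx,
                       mpaConfig(n = 1, seed = 1, eq11Literal = TRUE),
                       wideSpace(), cf = 0.25)
  expect_equal(as.vector(outL), 1.9375)
  # CF = 0 puts the whole population at the elite
  outC <- phase3Update(pin(1, 1, 3), 2, ctx, mpaConfig(n = 1, seed = 1),
                       wideSpace(), cf = 0)
  expect_equal(as.vector(outC), 2)
})

test_that("FADs effect leaves pinned degenerate cases unchanged and stays in bounds", {
  cfg <- mpaConfig(n = 2, fads = 0.2, seed = 1)
  space <- searchSpace(c(-1, -1), c(1, 1))
  prey <- matrix(c(0.5, -0.5, 0.2, -0.2), 2, 2)
  # r > FADs with r1 = r2 -> zero difference vector
  same <- fadsEffect(prey, list(r = c(0.9, 0.9), r1 = c(1, 2), r2 = c(1, 2)),
                     cfg, space, cf = 1)
  expect_equal(same, prey)
  # r <= FADs with U = 0 -> masked jump is zero
  masked <- fadsEffect(prey, list(r = c(0.1, 0.1), U = matrix(0, 2, 2)),
                       cfg, space, cf = 1)
  expect_equal(masked, prey)
  # containment over many random applications
  set.seed(3)
  p <- matrix(runif(100 * 2, -1, 1), 100, 2)
  for (i in 1:100) {
    p <- fadsEffect(p, list(), cfg, space, cf = 0.7)
    expect_true(all(p >= -1 & p <= 1))
  }
})

test_that("the phase schedule partitions the iterations into thirds", {
  for (iMax in c(1, 2, 3, 7, 9, 10, 100)) {
    phases <- vapply(0:(iMax - 1), mpaPhase, integer(1), iMax = iMax)
    expect_equal(sum(phases == 1), floor(iMax / 3))
    expect_equal(sum(phases == 2), floor(2 * iMax / 3) - floor(iMax / 3))
    expect_equal(sum(phases == 3), iMax - floor(2 * iMax / 3))
    expect_true(all(diff(phases) >= 0))   # each iteration exactly one phase
  }
})

test_that("optimizer is elitist, bound-feasible, reproducible, and handles edge cases", {
  obj <- benchmarkObjective("rastrigin", 3)
  seen <- new.env(); seen$ok <- TRUE
  fn <- function(x) {
    if (any(x < obj$space@lb) || any(x > obj$space@ub)) seen$ok <- FALSE
    obj$fn(x)
  }
  cfg <- mpaConfig(n = 12, iMax = 40, seed = 9)
  r1 <- mpaOptimize(fn, obj$space, cfg)
  expect_true(seen$ok)                          # every evaluated point in bounds
  expect_true(all(diff(fitnessHistory(r1)) <= 0))
  expect_equal(bestFitness(r1), min(fitnessHistory(r1)))
  expect_equal(r1@evals, 12L * 41L)
  r2 <- mpaOptimize(fn, obj$space, cfg)
  expect_identical(fitnessHistory(r1), fitnessHistory(r2))
  expect_identical(bestPosition(r1), bestPosition(r2))

  # iMax = 0 returns the best member of the initial population
  r0 <- mpaOptimize(obj$fn, obj$space, mpaConfig(n = 8, iMax = 0, seed = 4))
  init <- initPopulation(obj$space, mpaConfig(n = 8, iMax = 0, seed = 4))
  expect_equal(bestFitness(r0), min(apply(init, 1, obj$fn)))

  # degenerate 1-agent 1-D run respects all invariants
  s1 <- benchmarkObjective("sphere", 1)
  rd <- mpaOptimize(s1$fn, s1$space, mpaConfig(n = 1, iMax = 10, seed = 2))
  expect_true(all(diff(fitnessHistory(rd)) <= 0))

  # non-finite fitness is reported with the candidate
  expect_error(
    mpaOptimize(function(x) NaN, s1$space, mpaConfig(n = 2, iMax = 1, seed = 1)),
    "non-finite")
})

test_that("error-rate fitness arithmetic is exact", {
  y <- rep("a", 100); p <- y; p[1:3] <- "b"
  expect_equal(errorRatePercent(y, p), 3.0)
  expect_equal(errorRatePercent(y, y), 0.0)
  expect_equal(errorRatePercent(rep("a", 10), rep("b", 10)), 100.0)
})

test_that("candidate decoding respects the hyperparameter contract", {
  hp <- decodeCandidate(c(-2, -1.3, 63.6, 8.2, 2.7, 44.5))
  expect_equal(hp$rbmLr, 1e-2)
  expect_equal(hp$ftLr, 10^-1.3)
  expect_equal(hp$hidden, c(64L, 8L))
  expect_equal(hp$cdK, 3L)
  expect_equal(hp$ftEpochs, 44L)   # round-half-even on .5
  sp <- dbnSearchSpace()
  expect_equal(spaceDim(sp), 6L)
  # bounds produce valid architectures everywhere (no 0-unit layers)
  lo <- decodeCandidate(sp@lb)
  expect_true(all(lo$hidden >= 8), lo$cdK >= 1)
})

test_that("classifier-error fitness trains on inner-train and scores inner-validation", {
  blobs <- makeBlobs(nPerClass = 30, seed = 15)
  bundle <- makeTrainBundle(blobs$X, blobs$y, seed = 3, rbmEpochs = 3)
  expect_length(intersect(bundle$innerTrain, bundle$innerVal), 0)
  expect_setequal(c(bundle$innerTrain, bundle$innerVal), seq_along(blobs$y))
  f <- classifierErrorFitness(c(-1.5, -1, 16, 8, 1, 20), dbnSearchSpace(), bundle)
  expect_gte(f, 0); expect_lte(f, 100)
  # deterministic for a fixed bundle
  f2 <- classifierErrorFitness(c(-1.5, -1, 16, 8, 1, 20), dbnSearchSpace(), bundle)
  expect_identical(f, f2)
  expect_error(classifierErrorFitness(rep(99, 6), dbnSearchSpace(), bundle),
               "out of bounds")
})
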