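## Marine Predators Algorithm (MPA): a population metaheuristic alternating
## Brownian and Levy-flight moves across three velocity-ratio phases, with an
## occasional FADs (fish-aggregating-devices) long jump to escape local
## optima. Lower fitness is better throughout.

#' Initialize the prey population uniformly within bounds
#'
#' Each coordinate j of each agent is drawn uniformly on [lb_j, ub_j].
#'
#' @param space a [SearchSpace-class].
#' @param cfg an [MPAConfig-class]; `cfg@seed` makes the draw reproducible.
#' @return n x d numeric matrix of positions.
#' @export
initPopulation <- function(space, cfg) {
  d <- spaceDim(space)
  withLocalSeed(cfg@seed, {
    u <- matrix(runif(cfg@n * d), cfg@n, d)
    sweep(sweep(u, 2, space@ub - space@lb, "*"), 2, space@lb, "+")
  })
}

#' Adaptive step-scale CF
#'
#' `CF = (1 - I/Imax)^(2 I / Imax)`: 1 at the first iteration, 0 at the last,
#' monotonically non-increasing in between. It shrinks predator moves as the
#' search turns from exploration to exploitation.
#'
#' @param i current iteration (0-based, `0 <= i <= iMax`).
#' @param iMax maximal iterations (>= 1).
#' @return scalar in [0, 1].
#' @export
computeCF <- function(i, iMax) {
  stopifnot(iMax >= 1)
  if (i > iMax || i < 0) stop("iteration i must satisfy 0 <= i <= iMax")
  (1 - i / iMax)^(2 * i / iMax)
}

#' Levy-stable random draws (Mantegna's algorithm)
#'
#' Heavy-tailed steps with stability exponent `alpha`; the tail index of
#' |draws| approaches `alpha`. Uses the current RNG stream.
#'
#' @param n number of draws.
#' @param alpha stability exponent in (1, 2].
#' @return numeric vector of length n.
#' @export
levyVector <- function(n, alpha = 1.5) {
  stopifnot(alpha > 1, alpha <= 2)
  num <- gamma(1 + alpha) * sin(pi * alpha / 2)
  den <- gamma((1 + alpha) / 2) * alpha * 2^((alpha - 1) / 2)
  sigmaU <- (num / den)^(1 / alpha)
  u <- rnorm(n, sd = sigmaU)
  v <- rnorm(n)
  u / abs(v)^(1 / alpha)
}

## Random-draw context for one iteration; tests may pin any component.
makeStepContext <- function(n, d, alpha) {
  list(RB = matrix(rnorm(n * d), n, d),
       RL = matrix(levyVector(n * d, alpha), n, d),
       R  = matrix(runif(n * d), n, d))
}

#' Phase 1 update: high-velocity-ratio exploration
#'
#' First third of the iterations. For every agent:
#' `Step = RB (*) (Elite - RB (*) Prey)`, `Prey <- Prey + P * R (*) Step`,
#' with `RB` Brownian (standard normal) and `R` uniform draws, then clamped
#' to the bounds.
#'
#' @param prey n x d position matrix.
#' @param elite length-d top-predator vector.
#' @param ctx list with matrices `RB`, `R` (and `RL`) as from the internal
#'   draw helper; exposed so degenerate draws can be injected.
#' @param cfg an [MPAConfig-class].
#' @param space a [SearchSpace-class].
#' @return updated n x d matrix.
#' @export
phase1Update <- function(prey, elite, ctx, cfg, space) {
  em <- matrix(elite, nrow(prey), ncol(prey), byrow = TRUE)
  step <- ctx$RB * (em - ctx$RB * prey)
  clampToBounds(prey + cfg@p * ctx$R * step, space@lb, space@ub)
}

#' Phase 2 update: unit-velocity-ratio transition
#'
#' Middle third. The first half of the population (ceiling(n/2) agents)
#' keeps exploring with Levy steps:
#' `Step = RL (*) (Elite - RL (*) Prey)`, `Prey <- Prey + P * R (*) Step`.
#' The second half exploits around the elite with Brownian steps:
#' `Step = RB (*) Elite - RB (*) Prey`, `Prey <- Elite + P * CF * Step`.
#'
#' @inheritParams phase1Update
#' @param cf adaptive scalar from [computeCF()].
#' @export
phase2Update <- function(prey, elite, ctx, cfg, space, cf) {
  n <- nrow(prey)
  em <- matrix(elite, n, ncol(prey), byrow = TRUE)
  half <- ceiling(n / 2)
  out <- prey
  i1 <- seq_len(half)
  step1 <- ctx$RL[i1, , drop = FALSE] *
    (em[i1, , drop = FALSE] - ctx$RL[i1, , drop = FALSE] * prey[i1, , drop = FALSE])
  out[i1, ] <- prey[i1, , drop = FALSE] +
    cfg@p * ctx$R[i1, , drop = FALSE] * step1
  if (half < n) {
    i2 <- (half + 1L):n
    step2 <- ctx$RB[i2, , drop = FALSE] * em[i2, , drop = FALSE] -
      ctx$RB[i2, , drop = FALSE] * prey[i2, , drop = FALSE]
    out[i2, ] <- em[i2, , drop = FALSE] + cfg@p * cf * step2
  }
  clampToBounds(out, space@lb, space@ub)
}

#' Phase 3 update: low-velocity-ratio exploitation
#'
#' Final third. All agents move around the elite with Levy steps:
#' `Step = RL (*) (RL (*) Elite - Prey)`, `Prey <- Elite + P * CF * Step`.
#' With `cfg@eq11Literal = TRUE` the inner Levy factor is dropped
#' (`Step = RL (*) (Elite - Prey)`).
#'
#' @inheritParams phase2Update
#' @export
phase3Update <- function(prey, elite, ctx, cfg, space, cf) {
  em <- matrix(elite, nrow(prey), ncol(prey), byrow = TRUE)
  step <- if (cfg@eq11Literal) ctx$RL * (em - prey)
          else ctx$RL * (ctx$RL * em - prey)
  clampToBounds(em + cfg@p * cf * step, space@lb, space@ub)
}

#' FADs effect: occasional long jumps
#'
#' Per agent, with probability `cfg@fads` the agent takes a masked random
#' long jump `Prey <- Prey + CF * (lb + R (*) (ub - lb)) (*) U` (U a
#' Bernoulli(`cfg@fads`) per-coordinate mask); otherwise it moves along the
#' difference of two random population members,
#' `Prey <- Prey + (FADs (1 - r) + r) (Prey_r1 - Prey_r2)`. Clamped to
#' bounds.
#'
#' @inheritParams phase2Update
#' @param ctx optionally carries `r` (per-agent uniforms), `U` (n x d binary
#'   mask), `r1`, `r2` (permutation indices) and `R`; missing components are
#'   drawn.
#' @export
fadsEffect <- function(prey, ctx, cfg, space, cf) {
  n <- nrow(prey); d <- ncol(prey)
  r <- if (!is.null(ctx$r)) ctx$r else runif(n)
  U <- if (!is.null(ctx$U)) ctx$U else
    matrix(as.numeric(runif(n * d) < cfg@fads), n, d)
  Rm <- if (!is.null(ctx$R)) ctx$R else matrix(runif(n * d), n, d)
  r1 <- if (!is.null(ctx$r1)) ctx$r1 else sample.int(n, n, replace = TRUE)
  r2 <- if (!is.null(ctx$r2)) ctx$r2 else sample.int(n, n, replace = TRUE)
  out <- prey
  lbm <- matrix(space@lb, n, d, byrow = TRUE)
  ubm <- matrix(space@ub, n, d, byrow = TRUE)
  jumpers <- r <= cfg@fads
  if (any(jumpers)) {
    jump <- cf * (lbm + Rm * (ubm - lbm)) * U
    out[jumpers, ] <- prey[jumpers, , drop = FALSE] + jump[jumpers, , drop = FALSE]
  }
  if (any(!jumpers)) {
    idx <- which(!jumpers)
    coef <- cfg@fads * (1 - r[idx]) + r[idx]
    diff <- prey[r1[idx], , drop = FALSE] - prey[r2[idx], , drop = FALSE]
    out[idx, ] <- prey[idx, , drop = FALSE] + coef * diff
  }
  clampToBounds(out, space@lb, space@ub)
}

#' Phase of the schedule for a given iteration
#'
#' Iterations `0 .. floor(iMax/3) - 1` are phase 1 (exploration), the next
#' third phase 2 (transition), and the remainder phase 3 (exploitation). The
#' three ranges partition `0 .. iMax - 1` exactly.
#'
#' @param i 0-based iteration index.
#' @param iMax total iterations.
#' @return 1, 2 or 3.
#' @export
mpaPhase <- function(i, iMax) {
  if (i < floor(iMax / 3)) 1L else if (i < floor(2 * iMax / 3)) 2L else 3L
}

#' Run the Marine Predators Algorithm
#'
#' Minimizes `fitness` over the box `space`. After the initial evaluation,
#' each of the `iMax` iterations applies the phase update for its third of
#' the schedule (exploration, transition, exploitation), the FADs
#' perturbation, re-evaluation, per-agent memory saving (an agent's previous
#' position is restored if it was fitter), and the elite update (strict
#' improvement only). The returned history is therefore non-increasing.
#'
#' @param fitness function mapping an in-bounds d-vector to a finite scalar
#'   (lower is better).
#' @param space a [SearchSpace-class].
#' @param cfg an [MPAConfig-class].
#' @param verbose log per-iteration progress.
#' @return an [OptimizeResult-class].
#' @examples
#' obj <- benchmarkObjective("sphere", 5)
#' res <- mpaOptimize(obj$fn, obj$space, mpaConfig(n = 10, iMax = 50, seed = 1))
#' bestFitness(res)
#' @export
mpaOptimize <- function(fitness, space, cfg, verbose = FALSE) {
  d <- spaceDim(space)
  evalAll <- function(pos) {
    f <- apply(pos, 1, fitness)
    bad <- !is.finite(f)
    if (any(bad))
      stop("fitness returned a non-finite value at candidate [",
           paste(signif(pos[which(bad)[1], ], 4), collapse = ", "), "]")
    f
  }

  prey <- initPopulation(space, cfg)
  withLocalSeed(deriveSeed(cfg@seed, 1L), {
    fit <- evalAll(prey)
    evals <- cfg@n
    bestI <- which.min(fit)
    elite <- prey[bestI, ]
    eliteF <- fit[bestI]
    history <- eliteF

    if (cfg@iMax > 0L) {
      for (iter in 0:(cfg@iMax - 1L)) {
        cf <- computeCF(iter, cfg@iMax)
        ctx <- makeStepContext(cfg@n, d, cfg@levyAlpha)
        ph <- mpaPhase(iter, cfg@iMax)
        prey2 <-
          if (ph == 1L) phase1Update(prey, elite, ctx, cfg, space)
          else if (ph == 2L) phase2Update(prey, elite, ctx, cfg, space, cf)
          else phase3Update(prey, elite, ctx, cfg, space, cf)
        prey2 <- fadsEffect(prey2, list(), cfg, space, cf)
        fit2 <- evalAll(prey2)
        evals <- evals + cfg@n
        # memory saving: keep the fitter of old/new per agent
        worse <- fit2 > fit
        prey2[worse, ] <- prey[worse, , drop = FALSE]
        fit2[worse] <- fit[worse]
        prey <- prey2; fit <- fit2
        # elite update on strict improvement
        bestI <- which.min(fit)
        if (fit[bestI] < eliteF) {
          eliteF <- fit[bestI]
          elite <- prey[bestI, ]
        }
        history <- c(history, eliteF)
        if (verbose) logStage("mpa", sprintf("iter %d best %.6g", iter + 1L, eliteF))
      }
    }
    new("OptimizeResult", bestX = as.numeric(elite), bestF = eliteF,
        history = history, evals = as.integer(evals))
  })
}

#' Search space for the classifier hyperparameters
#'
#' Six coordinates decoded by [decodeCandidate()]: log10 RBM learning rate
#' and log10 fine-tune learning rate on [-4, -1]; hidden layer 1 and 2 sizes
#' on [8, 256] (rounded); contrastive-divergence steps k on [1, 5] (rounded);
#' fine-tune epochs on [5, 60] (rounded).
#'
#' @return a [SearchSpace-class] with d = 6.
#' @export
dbnSearchSpace <- function() {
  searchSpace(
    lb = c(-4, -4, 8, 8, 1, 5),
    ub = c(-1, -1, 256, 256, 5, 60),
    kinds = c("log_scale", "log_scale", "integer", "integer", "integer",
              "integer"))
}

#' Decode a continuous candidate into DBN hyperparameters
#'
#' @param candidate numeric vector in the bounds of [dbnSearchSpace()].
#' @return list with `rbmLr`, `ftLr`, `hidden` (length 2), `cdK`, `ftEpochs`.
#' @export
decodeCandidate <- function(candidate) {
  stopifnot(length(candidate) == 6L)
  list(rbmLr = 10^candidate[1],
       ftLr = 10^candidate[2],
       hidden = c(max(8L, as.integer(round(candidate[3]))),
                  max(8L, as.integer(round(candidate[4])))),
       cdK = max(1L, as.integer(round(candidate[5]))),
       ftEpochs = max(0L, as.integer(round(candidate[6]))))
}

#' Bundle training data for the hyperparameter-tuning fitness
#'
#' Holds standardized training features and labels with a stratified inner
#' train/validation split, so the tuner's error rate is computed on data the
#' candidate's classifier never saw — and the outer test split is never
#' touched.
#'
#' @param X standardized n x d training feature matrix.
#' @param y length-n training labels.
#' @param classes full class label set.
#' @param valFraction inner validation fraction (default 0.2).
#' @param seed integer seed for the inner split and for classifier training.
#' @param rbmEpochs pretraining epochs used inside the fitness.
#' @return list consumed by [classifierErrorFitness()].
#' @export
makeTrainBundle <- function(X, y, classes = sort(unique(y)), valFraction = 0.2,
                            seed = 1L, rbmEpochs = 10L) {
  sp <- splitDataset(y, trainFraction = 1 - valFraction, stratified = TRUE,
                     seed = deriveSeed(seed, 17L))
  list(X = X, y = y, classes = classes, innerTrain = sp$train,
       innerVal = sp$test, seed = seed, rbmEpochs = as.integer(rbmEpochs))
}

#' Classification error rate as a percentage
#'
#' `misclassified / total * 100`, the quantity the hyperparameter tuner
#' minimizes.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @return percentage in [0, 100].
#' @export
errorRatePercent <- function(yTrue, yPred) {
  stopifnot(length(yTrue) == length(yPred), length(yTrue) > 0)
  sum(yPred != yTrue) / length(yTrue) * 100
}

#' Classifier-error fitness for hyperparameter tuning
#'
#' Decodes the candidate into DBN hyperparameters, trains a DBN on the inner
#' training portion of the bundle, and returns the validation error rate as a
#' percentage: `misclassified / total * 100`, in [0, 100]. Lower is better.
#' Deterministic for a fixed bundle (training is seeded from the bundle, and
#' the caller's RNG stream is untouched).
#'
#' @param candidate length-6 numeric vector within [dbnSearchSpace()].
#' @param space the search space (bounds check).
#' @param bundle list from [makeTrainBundle()].
#' @return error percentage in [0, 100].
#' @export
classifierErrorFitness <- function(candidate, space, bundle) {
  if (any(candidate < space@lb - 1e-9) || any(candidate > space@ub + 1e-9))
    stop("candidate out of bounds")
  hp <- decodeCandidate(candidate)
  tr <- bundle$innerTrain
  model <- dbnTrain(bundle$X[tr, , drop = FALSE], bundle$y[tr],
                    hidden = hp$hidden, cdK = hp$cdK, rbmLr = hp$rbmLr,
                    rbmEpochs = bundle$rbmEpochs, ftLr = hp$ftLr,
                    ftEpochs = hp$ftEpochs, seed = bundle$seed,
                    classes = bundle$classes)
  pred <- predict(model, bundle$X[bundle$innerVal, , drop = FALSE])
  errorRatePercent(bundle$y[bundle$innerVal], pred$labels)
}
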