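#' Stratified train/test split
#'
#' @param labels length-n class labels.
#' @param trainFraction fraction assigned to training, in (0, 1).
#' @param stratified split within each class (requires >= 2 samples per
#'   class).
#' @param seed integer seed.
#' @return list with disjoint, exhaustive integer index vectors `train` and
#'   `test`.
#' @export
splitDataset <- function(labels, trainFraction = 0.8, stratified = TRUE,
                         seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  n <- length(labels)
  withLocalSeed(seed, {
    if (stratified) {
      counts <- table(labels)
      if (any(counts < 2L))
        stop("stratified split needs >= 2 samples per class; offending: ",
             paste(names(counts)[counts < 2L], collapse = ", "))
      train <- integer(0)
      for (cl in names(counts)) {
        idx <- which(labels == cl)
        k <- round(length(idx) * trainFraction)
        k <- min(max(k, 1L), length(idx) - 1L)   # both sides non-empty
        train <- c(train, sample(idx, k))
      }
      train <- sort(train)
    } else {
      train <- sort(sample.int(n, round(n * trainFraction)))
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config layout: sections `data`,
#' `preprocess`, `features`, `ae`, `mpa`, `dbn`, `split`, `output`, plus the
#' top-level `seed` and `tune` switches.
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    tune = TRUE,
    data = list(dir = NULL, synthetic = TRUE, nPerClass = 60L, tileSize = 64L),
    preprocess = list(clipLimit = 2.0, blockSize = c(8L, 8L), nBins = 256L,
                      colorMode = "lab_l"),
    features = list(inputSize = c(64L, 64L), channels = c(3L, 16L, 32L, 64L, 64L),
                    strides = c(1L, 2L, 1L, 2L), kernel = 3L,
                    weightsMode = "random_fixed"),
    ae = list(enabled = FALSE, bottleneck = 16L, lr = 0.05, epochs = 30L),
    mpa = list(n = 6L, iMax = 6L, p = 0.5, fads = 0.2, levyAlpha = 1.5),
    dbn = list(hidden = c(64L, 32L), cdK = 1L, rbmLr = 0.05, rbmEpochs = 10L,
               ftLr = 0.1, ftEpochs = 60L),
    split = list(trainFraction = 0.8, stratified = TRUE),
    output = list(dir = NULL)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [defaultPipelineConfig()].
#'
#' @param path YAML file.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeCfg <- function(def, usr) {
    for (k in names(usr)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(usr[[k]]))
        mergeCfg(def[[k]], usr[[k]]) else usr[[k]]
    }
    def
  }
  mergeCfg(defaultPipelineConfig(), user)
}

#' Run the full classification pipeline
#'
#' CLAHE preprocessing, depthwise-separable feature extraction,
#' standardization fitted on the training split only, optional autoencoder
#' compression (trained on the training split only), MPA hyperparameter
#' search with the classifier-error fitness on an inner validation split,
#' final DBN retraining on the full training split with the best
#' hyperparameters, and one-vs-rest evaluation on the test split. The test
#' split never enters standardization fitting, AE training, MPA fitness or
#' DBN training; the returned `provenance` records the index bookkeeping.
#'
#' @param config list as from [defaultPipelineConfig()] /
#'   [readPipelineConfig()].
#' @param tiles optional list of labeled [ImageTile-class]; when NULL,
#'   synthetic tiles are generated (config `data$synthetic`) or loaded from
#'   `data$dir`.
#' @param verbose log stages.
#' @return list with `report` ([MetricsReport-class]), `best` (hyperparameter
#'   list), `tuning` ([OptimizeResult-class] or NULL), `predictions`
#'   (data.frame id/true/pred/score columns), `split`, `provenance`, and
#'   `elapsed` (seconds).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), tiles = NULL,
                        verbose = TRUE) {
  t0 <- proc.time()["elapsed"]
  seed <- as.integer(config$seed)

  logStage("data", "seed=", seed, verbose = verbose)
  if (is.null(tiles)) {
    tiles <- if (!is.null(config$data$dir)) {
      loadTiles(config$data$dir)
    } else if (isTRUE(config$data$synthetic)) {
      generateTiles(config$data$nPerClass, size = config$data$tileSize,
                    seed = deriveSeed(seed, 2L))
    } else stop("stage data: no tile source (set data$dir or data$synthetic)")
  }
  labels <- tileLabels(tiles)
  if (anyNA(labels)) stop("stage data: all tiles must be labeled")
  classes <- sort(unique(labels))

  logStage("preprocess", "CLAHE on ", length(tiles), " tiles", verbose = verbose)
  pc <- config$preprocess
  ccfg <- claheConfig(clipLimit = pc$clipLimit, blockSize = pc$blockSize,
                      nBins = pc$nBins, colorMode = pc$colorMode)
  enhanced <- lapply(tiles, claheEnhance, cfg = ccfg)

  logStage("split", verbose = verbose)
  sp <- splitDataset(labels, trainFraction = config$split$trainFraction,
                     stratified = isTRUE(config$split$stratified),
                     seed = deriveSeed(seed, 5L))

  logStage("features", verbose = verbose)
  fc <- config$features
  ecfg <- extractorConfig(inputSize = fc$inputSize, channels = fc$channels,
                          strides = fc$strides, kernel = fc$kernel,
                          weightsSeed = deriveSeed(seed, 3L),
                          weightsMode = fc$weightsMode)
  fm <- extractFeatures(enhanced, ecfg, trainRows = sp$train)
  fm <- standardizeFeatures(fm, fitRows = sp$train)
  X <- featureValues(fm)

  aeModel <- NULL
  if (isTRUE(config$ae$enabled)) {
    logStage("autoencoder", "bottleneck=", config$ae$bottleneck, verbose = verbose)
    dims <- c(ncol(X), max(config$ae$bottleneck * 2L, config$ae$bottleneck + 1L),
              config$ae$bottleneck)
    aeModel <- trainAutoencoder(X[sp$train, , drop = FALSE], dims,
                                lr = config$ae$lr, epochs = config$ae$epochs,
                                seed = deriveSeed(seed, 7L))
    X <- aeEncode(aeModel, X)
  }

  tuning <- NULL
  if (isTRUE(config$tune)) {
    logStage("mpa", "n=", config$mpa$n, " iMax=", config$mpa$iMax,
             verbose = verbose)
    bundle <- makeTrainBundle(X[sp$train, , drop = FALSE], labels[sp$train],
                              classes = classes, seed = deriveSeed(seed, 11L),
                              rbmEpochs = config$dbn$rbmEpochs)
    space <- dbnSearchSpace()
    mcfg <- mpaConfig(n = config$mpa$n, iMax = config$mpa$iMax,
                      p = config$mpa$p, fads = config$mpa$fads,
                      levyAlpha = config$mpa$levyAlpha,
                      seed = deriveSeed(seed, 13L))
    tuning <- mpaOptimize(function(x) classifierErrorFitness(x, space, bundle),
                          space, mcfg, verbose = verbose)
    best <- decodeCandidate(bestPosition(tuning))
  } else {
    logStage("mpa", "tuning disabled; using config defaults", verbose = verbose)
    best <- list(rbmLr = config$dbn$rbmLr, ftLr = config$dbn$ftLr,
                 hidden = config$dbn$hidden, cdK = config$dbn$cdK,
                 ftEpochs = config$dbn$ftEpochs)
  }

  logStage("dbn", "hidden=", paste(best$hidden, collapse = "x"),
           " k=", best$cdK, verbose = verbose)
  model <- dbnTrain(X[sp$train, , drop = FALSE], labels[sp$train],
                    hidden = best$hidden, cdK = best$cdK, rbmLr = best$rbmLr,
                    rbmEpochs = config$dbn$rbmEpochs, ftLr = best$ftLr,
                    ftEpochs = best$ftEpochs, seed = deriveSeed(seed, 19L),
                    classes = classes)

  logStage("evaluate", verbose = verbose)
  pred <- predict(model, X[sp$test, , drop = FALSE])
  report <- evaluateClassifier(labels[sp$test], pred$labels,
                               yScores = pred$probabilities, labels = classes)

  predictions <- data.frame(
    id = vapply(tiles[sp$test], function(t) t@sourceId, character(1)),
    true = labels[sp$test], pred = pred$labels,
    stringsAsFactors = FALSE)
  predictions <- cbind(predictions,
                       as.data.frame(pred$probabilities,
                                     col.names = paste0("score_", classes)))
  names(predictions)[-(1:3)] <- paste0("score_", classes)

  provenance <- list(
    seed = seed,
    classes = classes,
    trainIndices = sp$train, testIndices = sp$test,
    standardizationFitRows = fm@fitRows,
    aeTrainRows = if (is.null(aeModel)) integer(0) else sp$train,
    fitnessRows = if (is.null(tuning)) integer(0) else sp$train,
    dbnTrainRows = sp$train)

  elapsed <- as.numeric(proc.time()["elapsed"] - t0)
  logStage("done", sprintf("%.1fs, macro accuracy %.2f%%", elapsed,
                           100 * macroMetrics(report)["accuracy"]),
           verbose = verbose)

  result <- list(report = report, best = best, tuning = tuning,
                 predictions = predictions, split = sp,
                 provenance = provenance, config = config, elapsed = elapsed)
  if (!is.null(config$output$dir)) writePipelineArtifacts(result, config$output$dir)
  result
}

#' Write pipeline artifacts
#'
#' Emits `metrics.json`, `confusion.csv`, `convergence.csv` (when tuned),
#' `preds.csv` and a `config_echo.yaml` provenance copy.
#'
#' @param result list returned by [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writePipelineArtifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- result$report
  metrics <- list(perClass = perClassMetrics(rep),
                  macro = as.list(macroMetrics(rep)),
                  microAccuracy = microAccuracy(rep),
                  nTest = rep@nTest, seed = result$provenance$seed,
                  best = result$best, elapsedSeconds = result$elapsed)
  paths <- c(
    metrics = file.path(dir, "metrics.json"),
    confusion = file.path(dir, "confusion.csv"),
    preds = file.path(dir, "preds.csv"),
    config = file.path(dir, "config_echo.yaml"))
  jsonlite::write_json(metrics, paths["metrics"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(confusionMatrix(rep)), paths["confusion"])
  utils::write.csv(result$predictions, paths["preds"], row.names = FALSE)
  yaml::write_yaml(result$config, paths["config"])
  if (!is.null(result$tuning)) {
    cv <- file.path(dir, "convergence.csv")
    utils::write.csv(data.frame(iteration = seq_along(fitnessHistory(result$tuning)) - 1L,
                                best = fitnessHistory(result$tuning)),
                     cv, row.names = FALSE)
    paths <- c(paths, convergence = cv)
  }
  invisible(paths)
}
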