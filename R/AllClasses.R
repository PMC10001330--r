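#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

# ---------------------------------------------------------------------------
# ImageTile
# ---------------------------------------------------------------------------

#' ImageTile: one labeled RGB histology tile
#'
#' Holds an H x W x 3 array of integer intensities in [0, 255], an optional
#' class label, and an opaque source identifier (typically the file path or a
#' synthetic-recipe tag).
#'
#' @slot pixels numeric H x W x 3 array, integer-valued intensities in
#'   [0, 255].
#' @slot label character scalar class label, or `NA_character_` if unlabeled.
#' @slot sourceId character scalar identifying the tile's origin.
#' @export
setClass("ImageTile",
  representation(pixels = "array", label = "character", sourceId = "character"),
  prototype(label = NA_character_, sourceId = "")
)

setValidity("ImageTile", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel intensities must lie in [0, 255]")
  if (length(object@label) != 1L) return("label must be a single string (or NA)")
  TRUE
})

#' Construct an ImageTile
#'
#' @param pixels H x W x 3 array of intensities in [0, 255].
#' @param label optional class label.
#' @param sourceId optional origin identifier.
#' @return an [ImageTile-class] object.
#' @export
imageTile <- function(pixels, label = NA_character_, sourceId = "") {
  new("ImageTile", pixels = round(pixels), label = as.character(label),
      sourceId = as.character(sourceId))
}

# ---------------------------------------------------------------------------
# Configs
# ---------------------------------------------------------------------------

#' CLAHE configuration
#'
#' @slot clipLimit positive clip limit, a multiple of the uniform histogram
#'   bin height (`Inf` disables clipping).
#' @slot blockSize integer (rows, cols): the grid of contextual blocks.
#' @slot nBins number of histogram bins.
#' @slot colorMode `"lab_l"` (equalize CIELAB L only, preserving stain hue) or
#'   `"per_channel"` (equalize each RGB channel independently).
#' @export
setClass("ClaheConfig",
  representation(clipLimit = "numeric", blockSize = "integer",
                 nBins = "integer", colorMode = "character"))

setValidity("ClaheConfig", function(object) {
  if (object@clipLimit <= 0) return("clipLimit must be > 0")
  if (length(object@blockSize) != 2L || any(object@blockSize < 1L))
    return("blockSize must be two integers >= 1")
  if (object@nBins < 2L) return("nBins must be >= 2")
  if (!object@colorMode %in% c("lab_l", "per_channel"))
    return("colorMode must be 'lab_l' or 'per_channel'")
  TRUE
})

#' @param clipLimit,blockSize,nBins,colorMode see slots of
#'   [ClaheConfig-class].
#' @rdname ClaheConfig-class
#' @export
claheConfig <- function(clipLimit = 2.0, blockSize = c(8L, 8L), nBins = 256L,
                        colorMode = c("lab_l", "per_channel")) {
  new("ClaheConfig", clipLimit = as.numeric(clipLimit),
      blockSize = as.integer(blockSize), nBins = as.integer(nBins),
      colorMode = match.arg(colorMode))
}

#' Feature-extractor configuration
#'
#' Defines a small stack of depthwise-separable convolution blocks ending in
#' global average pooling. `channels` is the channel chain (first entry is the
#' input channel count, 3 for RGB); `strides` has one entry per block.
#'
#' @slot inputSize integer (H, W) the tile is resized to before extraction.
#' @slot channels integer channel chain, length nblocks + 1.
#' @slot strides integer per-block stride, each 1 or 2.
#' @slot kernel odd integer depthwise kernel size.
#' @slot weightsSeed integer seed for the fixed random weights.
#' @slot weightsMode `"random_fixed"` or `"trained"`.
#' @slot widthMult width multiplier applied to all non-input channel counts.
#' @export
setClass("ExtractorConfig",
  representation(inputSize = "integer", channels = "integer",
                 strides = "integer", kernel = "integer",
                 weightsSeed = "integer", weightsMode = "character",
                 widthMult = "numeric"))

setValidity("ExtractorConfig", function(object) {
  if (length(object@channels) < 2L) return("need at least one block")
  if (length(object@strides) != length(object@channels) - 1L)
    return("strides must have one entry per block")
  if (!all(object@strides %in% c(1L, 2L))) return("strides must be 1 or 2")
  if (object@kernel %% 2L == 0L) return("kernel must be odd")
  if (!object@weightsMode %in% c("random_fixed", "trained"))
    return("weightsMode must be 'random_fixed' or 'trained'")
  if (object@widthMult <= 0) return("widthMult must be > 0")
  TRUE
})

#' @param inputSize,channels,strides,kernel,weightsSeed,weightsMode,widthMult
#'   see slots of [ExtractorConfig-class].
#' @rdname ExtractorConfig-class
#' @export
extractorConfig <- function(inputSize = c(64L, 64L),
                            channels = c(3L, 16L, 32L, 64L, 64L),
                            strides = c(1L, 2L, 1L, 2L), kernel = 3L,
                            weightsSeed = 20260101L,
                            weightsMode = c("random_fixed", "trained"),
                            widthMult = 1) {
  channels <- as.integer(channels)
  if (widthMult != 1) {
    channels[-1] <- pmax(1L, as.integer(round(channels[-1] * widthMult)))
  }
  new("ExtractorConfig", inputSize = as.integer(inputSize),
      channels = channels, strides = as.integer(strides),
      kernel = as.integer(kernel), weightsSeed = as.integer(weightsSeed),
      weightsMode = match.arg(weightsMode), widthMult = as.numeric(widthMult))
}

#' Feature dimension of an extractor configuration
#'
#' Equals the final block's output channel count (global average pooling).
#' @param cfg an [ExtractorConfig-class].
#' @return integer feature dimension.
#' @export
featureDim <- function(cfg) utils::tail(cfg@channels, 1L)

# ---------------------------------------------------------------------------
# FeatureMatrix
# ---------------------------------------------------------------------------

#' FeatureMatrix: per-tile feature vectors with standardization state
#'
#' @slot values n x d numeric matrix (rows = tiles).
#' @slot labels character labels per row (NA when unlabeled).
#' @slot ids character source ids per row.
#' @slot center,scale per-feature statistics fitted on the rows in `fitRows`,
#'   or NULL before standardization.
#' @slot fitRows integer indices the statistics were fitted on.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", labels = "character", ids = "character",
                 center = "numericOrNULL", scale = "numericOrNULL",
                 fitRows = "integer"),
  prototype(center = NULL, scale = NULL, fitRows = integer()))

setValidity("FeatureMatrix", function(object) {
  if (!all(is.finite(object@values))) return("feature values must be finite")
  if (length(object@labels) != nrow(object@values))
    return("one label per row required")
  TRUE
})

#' @describeIn FeatureMatrix-class numeric matrix of feature values.
#' @param x a FeatureMatrix.
#' @export
featureValues <- function(x) x@values

#' @describeIn FeatureMatrix-class per-row class labels.
#' @export
featureLabels <- function(x) x@labels

# ---------------------------------------------------------------------------
# MPA search space / config / result
# ---------------------------------------------------------------------------

#' Box-bounded search space for the optimizer
#'
#' @slot lb,ub numeric lower/upper bounds (lb < ub elementwise).
#' @slot kinds per-coordinate tag: "continuous", "integer" or "log_scale"
#'   (a hint for decoding; the optimizer itself works on the continuous box).
#' @export
setClass("SearchSpace",
  representation(lb = "numeric", ub = "numeric", kinds = "character"))

setValidity("SearchSpace", function(object) {
  if (length(object@lb) != length(object@ub)) return("lb/ub length mismatch")
  if (length(object@lb) < 1L) return("dimension must be >= 1")
  if (any(object@lb >= object@ub)) return("lb < ub required elementwise")
  if (length(object@kinds) != length(object@lb)) return("one kind per coordinate")
  if (!all(object@kinds %in% c("continuous", "integer", "log_scale")))
    return("kinds must be continuous/integer/log_scale")
  TRUE
})

#' @param lb,ub numeric bound vectors.
#' @param kinds optional per-coordinate tags (default all continuous).
#' @rdname SearchSpace-class
#' @export
searchSpace <- function(lb, ub, kinds = NULL) {
  if (is.null(kinds)) kinds <- rep("continuous", length(lb))
  new("SearchSpace", lb = as.numeric(lb), ub = as.numeric(ub),
      kinds = as.character(kinds))
}

#' Dimension of a search space
#' @param space a [SearchSpace-class].
#' @export
spaceDim <- function(space) length(space@lb)

#' Marine Predators Algorithm configuration
#'
#' @slot n population size.
#' @slot iMax maximal number of iterations.
#' @slot p step-size constant (0.5 in the standard formulation).
#' @slot fads probability of the fish-aggregating-devices long jump.
#' @slot levyAlpha stability exponent of the Levy-flight steps.
#' @slot seed integer RNG seed.
#' @slot eq11Literal if TRUE, the exploitation-phase step omits the inner
#'   Levy factor (the literal printed form of some MPA descriptions) instead
#'   of the self-consistent original rule.
#' @export
setClass("MPAConfig",
  representation(n = "integer", iMax = "integer", p = "numeric",
                 fads = "numeric", levyAlpha = "numeric", seed = "integer",
                 eq11Literal = "logical"))

setValidity("MPAConfig", function(object) {
  if (object@n < 1L) return("population size n must be >= 1")
  if (object@iMax < 0L) return("iMax must be >= 0")
  if (object@p <= 0) return("P must be > 0")
  if (object@fads < 0 || object@fads > 1) return("FADs must be in [0, 1]")
  if (object@levyAlpha <= 1 || object@levyAlpha > 2)
    return("levyAlpha must be in (1, 2]")
  TRUE
})

#' @param n,iMax,p,fads,levyAlpha,seed,eq11Literal see slots of
#'   [MPAConfig-class].
#' @rdname MPAConfig-class
#' @export
mpaConfig <- function(n = 25L, iMax = 100L, p = 0.5, fads = 0.2,
                      levyAlpha = 1.5, seed = 1L, eq11Literal = FALSE) {
  new("MPAConfig", n = as.integer(n), iMax = as.integer(iMax),
      p = as.numeric(p), fads = as.numeric(fads),
      levyAlpha = as.numeric(levyAlpha), seed = as.integer(seed),
      eq11Literal = isTRUE(eq11Literal))
}

#' Result of an optimizer run
#'
#' @slot bestX best position found.
#' @slot bestF its objective value (lower is better).
#' @slot history best-so-far objective after the initial evaluation and after
#'   each iteration; non-increasing by construction (elitism).
#' @slot evals total number of objective evaluations.
#' @export
setClass("OptimizeResult",
  representation(bestX = "numeric", bestF = "numeric", history = "numeric",
                 evals = "integer"))

setValidity("OptimizeResult", function(object) {
  h <- object@history
  if (length(h) && any(diff(h) > 0)) return("history must be non-increasing")
  if (length(h) && object@bestF != h[length(h)])
    return("bestF must equal the last history entry")
  TRUE
})

#' @describeIn OptimizeResult-class best position found.
#' @param x an OptimizeResult.
#' @export
bestPosition <- function(x) x@bestX

#' @describeIn OptimizeResult-class best objective value.
#' @export
bestFitness <- function(x) x@bestF

#' @describeIn OptimizeResult-class per-iteration best-so-far values.
#' @export
fitnessHistory <- function(x) x@history

# ---------------------------------------------------------------------------
# RBM / DBN / AE
# ---------------------------------------------------------------------------

#' Restricted Boltzmann machine parameters
#'
#' A bipartite energy model with `nrow(W)` visible and `ncol(W)` hidden
#' units. Visible units are Bernoulli or Gaussian (diagonal precision
#' `beta`); hidden units are Bernoulli.
#'
#' @slot W visible x hidden weight matrix.
#' @slot bVis visible bias vector.
#' @slot bHid hidden bias vector.
#' @slot visibleKind "bernoulli" or "gaussian".
#' @slot beta positive precision vector for Gaussian visibles.
#' @export
setClass("RBM",
  representation(W = "matrix", bVis = "numeric", bHid = "numeric",
                 visibleKind = "character", beta = "numeric"))

setValidity("RBM", function(object) {
  if (!all(is.finite(object@W))) return("weights must be finite")
  if (length(object@bVis) != nrow(object@W)) return("bVis length mismatch")
  if (length(object@bHid) != ncol(object@W)) return("bHid length mismatch")
  if (!object@visibleKind %in% c("bernoulli", "gaussian"))
    return("visibleKind must be bernoulli or gaussian")
  if (object@visibleKind == "gaussian" &&
      (length(object@beta) != nrow(object@W) || any(object@beta <= 0)))
    return("gaussian visibles need beta > 0 per visible unit")
  TRUE
})

#' Deep belief network classifier
#'
#' Greedily pretrained RBM stack whose weights initialize a feed-forward
#' sigmoid network, finished by a softmax head fine-tuned with
#' backpropagation.
#'
#' @slot rbms list of [RBM-class] layers, visible-to-hidden dims chaining.
#' @slot headW last-hidden x K softmax weight matrix.
#' @slot headB length-K softmax bias.
#' @slot classes the K class labels, in column order of `headW`.
#' @slot fineTune list with the learning rate and epoch counts used.
#' @export
setClass("DBNModel",
  representation(rbms = "list", headW = "matrix", headB = "numeric",
                 classes = "character", fineTune = "list"))

setValidity("DBNModel", function(object) {
  dims <- vapply(object@rbms, function(r) nrow(r@W), integer(1))
  outs <- vapply(object@rbms, function(r) ncol(r@W), integer(1))
  if (length(dims) > 1L && any(dims[-1] != outs[-length(outs)]))
    return("RBM layer dimensions must chain")
  if (nrow(object@headW) != outs[length(outs)])
    return("head input dim must equal last hidden dim")
  if (ncol(object@headW) != length(object@classes))
    return("head output dim must equal number of classes")
  TRUE
})

#' Stacked autoencoder
#'
#' Mirror-symmetric encoder/decoder trained to minimize mean squared
#' reconstruction error; sigmoid hidden layers, identity output layer.
#'
#' @slot encW,encB encoder weights/biases (lists, one per encoding layer).
#' @slot decW,decB decoder weights/biases (lists).
#' @slot dims full dimension chain input -> bottleneck.
#' @export
setClass("AEModel",
  representation(encW = "list", encB = "list", decW = "list", decB = "list",
                 dims = "integer"))

# ---------------------------------------------------------------------------
# MetricsReport
# ---------------------------------------------------------------------------

#' Multiclass evaluation report
#'
#' One-vs-rest per-class accuracy, precision, recall, F-score and ROC-AUC,
#' their unweighted macro averages, and the confusion matrix. All metrics are
#' stored as proportions in [0, 1]; `show()` prints percentages.
#'
#' @slot confusion K x K count matrix (rows = truth, cols = prediction).
#' @slot perClass data.frame with one row per class.
#' @slot macro named numeric vector of macro-averaged metrics.
#' @slot labels class labels.
#' @slot nTest number of evaluated samples.
#' @export
setClass("MetricsReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macro = "numeric", labels = "character", nTest = "integer"))

setValidity("MetricsReport", function(object) {
  if (sum(object@confusion) != object@nTest)
    return("confusion entries must sum to nTest")
  vals <- unlist(object@perClass[, c("accuracy", "precision", "recall", "f1")])
  if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE))
    return("per-class metrics must lie in [0, 1]")
  TRUE
})

#' @describeIn MetricsReport-class the K x K confusion matrix.
#' @param x a MetricsReport.
#' @export
confusionMatrix <- function(x) x@confusion

#' @describeIn MetricsReport-class per-class metric table (proportions).
#' @export
perClassMetrics <- function(x) x@perClass

#' @describeIn MetricsReport-class macro-averaged metrics (proportions).
#' @export
macroMetrics <- function(x) x@macro

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "ImageTile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageTile %dx%dx%d label=%s source=%s\n", d[1], d[2], d[3],
              object@label, object@sourceId))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d tiles x %d features (%s)\n",
              nrow(object@values), ncol(object@values),
              if (is.null(object@center)) "raw" else
                sprintf("standardized on %d rows", length(object@fitRows))))
})

setMethod("show", "OptimizeResult", function(object) {
  cat(sprintf("OptimizeResult: best f = %.6g after %d evaluations\n",
              object@bestF, object@evals))
})

setMethod("show", "RBM", function(object) {
  cat(sprintf("RBM: %d %s visible -> %d hidden units\n", nrow(object@W),
              object@visibleKind, ncol(object@W)))
})

setMethod("show", "DBNModel", function(object) {
  dims <- c(nrow(object@rbms[[1]]@W),
            vapply(object@rbms, function(r) ncol(r@W), integer(1)))
  cat(sprintf("DBNModel: %s -> softmax(%d classes)\n",
              paste(dims, collapse = "-"), length(object@classes)))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport on %d samples, %d classes\n", object@nTest,
              length(object@labels)))
  pc <- object@perClass
  num <- vapply(pc, is.numeric, logical(1))
  pc[num] <- lapply(pc[num], function(v) round(100 * v, 2))
  print(pc)
  cat("macro (%):\n")
  print(round(100 * object@macro, 2))
})
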