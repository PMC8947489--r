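#' @import methods
NULL

#' Parameters of the synthetic slide generator
#'
#' Describes one synthetic slide: canvas size, tissue geometry (elongated
#' needle-biopsy-like cores or rounded resection-like blobs), the fraction of
#' tissue carrying the planted lesion texture, the texture separation between
#' benign and lesion tissue, background gray level, and the seed from which
#' all randomness is derived.
#'
#' @slot imageSize integer, pixels per side at the nominal 20x scale.
#' @slot nCores integer, number of tissue pieces.
#' @slot coreShape `"needle"` (thin rotated rectangles, aspect >= 8:1) or
#'   `"blob"` (unions of discs).
#' @slot lesionFraction numeric in \[0, 1\]; fraction of tissue area carrying
#'   lesion texture. Zero if and only if the slide is benign.
#' @slot textureContrast numeric in (0, 95\]; controls how strongly the
#'   lesion's noise correlation length is shrunk relative to benign tissue,
#'   and bounds the tissue/background gray separation.
#' @slot backgroundLevel integer 8-bit gray level of the near-white background.
#' @slot seed integer master seed; identical parameters (including seed)
#'   produce bit-identical images.
#' @export
setClass("SynthParams", representation(
  imageSize = "integer", nCores = "integer", coreShape = "character",
  lesionFraction = "numeric", textureContrast = "numeric",
  backgroundLevel = "integer", seed = "integer"
))

setValidity("SynthParams", function(object) {
  msg <- character()
  if (object@imageSize < 64L) msg <- c(msg, "imageSize must be >= 64")
  if (object@nCores < 1L) msg <- c(msg, "nCores must be >= 1")
  if (!object@coreShape %in% c("needle", "blob"))
    msg <- c(msg, "coreShape must be 'needle' or 'blob'")
  if (object@lesionFraction < 0 || object@lesionFraction > 1)
    msg <- c(msg, "lesionFraction must be in [0, 1]")
  if (object@textureContrast <= 0 || object@textureContrast > 95)
    msg <- c(msg, "textureContrast must be in (0, 95]")
  if (object@backgroundLevel < 200L || object@backgroundLevel > 255L)
    msg <- c(msg, "backgroundLevel must be in [200, 255]")
  if (length(msg)) msg else TRUE
})

#' Construct synthetic-slide parameters
#'
#' @param imageSize pixels per side at the nominal 20x scale.
#' @param nCores number of tissue pieces.
#' @param coreShape `"needle"` or `"blob"`.
#' @param lesionFraction fraction of tissue area carrying lesion texture.
#' @param textureContrast benign/lesion texture separation (dimensionless).
#' @param backgroundLevel 8-bit background gray level.
#' @param seed integer master seed.
#' @return a [SynthParams-class] object.
#' @export
synthParams <- function(imageSize = 1024L, nCores = 3L,
                        coreShape = c("needle", "blob"),
                        lesionFraction = 0, textureContrast = 60,
                        backgroundLevel = 245L, seed = 1L) {
  new("SynthParams", imageSize = as.integer(imageSize),
      nCores = as.integer(nCores), coreShape = match.arg(coreShape),
      lesionFraction = lesionFraction, textureContrast = textureContrast,
      backgroundLevel = as.integer(backgroundLevel), seed = as.integer(seed))
}

setMethod("show", "SynthParams", function(object) {
  cat(sprintf(
    "SynthParams: %dpx, %d %s core(s), lesionFraction=%.3g, contrast=%.3g, bg=%d, seed=%d\n",
    object@imageSize, object@nCores, object@coreShape, object@lesionFraction,
    object@textureContrast, object@backgroundLevel, object@seed))
})

#' Tissue mask of one slide
#'
#' Binary per-pixel tissue/background map together with the Otsu threshold
#' that produced it. Tissue is defined as gray strictly below the threshold
#' (tissue is darker than the near-white background).
#'
#' @slot mask logical matrix, `TRUE` = tissue; dimensions equal the source.
#' @slot threshold integer 8-bit Otsu threshold.
#' @slot sourceSize integer `c(height, width)` of the source image.
#' @export
setClass("TissueMask", representation(
  mask = "matrix", threshold = "integer", sourceSize = "integer"
))

setValidity("TissueMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!identical(dim(object@mask), object@sourceSize))
    msg <- c(msg, "mask dimensions must equal sourceSize")
  if (object@threshold < 0L || object@threshold > 255L)
    msg <- c(msg, "threshold must be an 8-bit level")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask: %d x %d, Otsu threshold %d, %.1f%% tissue\n",
              object@sourceSize[1], object@sourceSize[2], object@threshold,
              100 * mean(object@mask)))
})

#' @describeIn TissueMask-class the logical tissue matrix.
#' @param x a `TissueMask`.
#' @export
maskMatrix <- function(x) x@mask

#' @describeIn TissueMask-class the 8-bit Otsu threshold.
#' @export
otsuLevel <- function(x) x@threshold

#' Per-tile positive-class probabilities on a fixed grid
#'
#' @slot slideId character slide identifier.
#' @slot tileSize integer tile side in pixels.
#' @slot stride integer grid stride in pixels.
#' @slot tiles data.frame with columns `x, y, tile_size, tissue_fraction,
#'   prob`; one row per grid tile, probabilities in \[0, 1\].
#' @export
setClass("TileProbabilityMap", representation(
  slideId = "character", tileSize = "integer", stride = "integer",
  tiles = "data.frame"
))

setValidity("TileProbabilityMap", function(object) {
  msg <- character()
  need <- c("x", "y", "tile_size", "prob")
  if (!all(need %in% names(object@tiles)))
    msg <- c(msg, paste("tiles must have columns", paste(need, collapse = ", ")))
  else if (nrow(object@tiles) &&
           (any(object@tiles$prob < 0) || any(object@tiles$prob > 1)))
    msg <- c(msg, "probabilities must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TileProbabilityMap", function(object) {
  cat(sprintf("TileProbabilityMap: slide %s, %d tiles (%dpx, stride %d), max p = %.4f\n",
              object@slideId, nrow(object@tiles), object@tileSize,
              object@stride, if (nrow(object@tiles)) max(object@tiles$prob) else NA))
})

#' @describeIn TileProbabilityMap-class tile table with probabilities.
#' @param x a `TileProbabilityMap`.
#' @export
tileProbs <- function(x) x@tiles

#' Hard-mining configuration
#'
#' @slot k integer, tiles selected per slide during mining.
#' @slot N integer, training-subset size that triggers a training run.
#' @slot batchSize integer, tiles per training batch.
#' @slot numLabels integer, number of labels (2 for the binary task).
#' @slot switchPatience integer, epochs without validation improvement
#'   before switching from random balanced sampling to hard mining.
#' @export
setClass("MiningConfig", representation(
  k = "integer", N = "integer", batchSize = "integer",
  numLabels = "integer", switchPatience = "integer"
))

setValidity("MiningConfig", function(object) {
  msg <- character()
  vals <- c(object@k, object@N, object@batchSize, object@numLabels,
            object@switchPatience)
  if (any(vals < 1L)) msg <- c(msg, "all fields must be positive integers")
  if (object@batchSize %% object@numLabels != 0L)
    msg <- c(msg, "batchSize must be divisible by numLabels")
  if (object@k > object@N) msg <- c(msg, "k must be <= N")
  if (length(msg)) msg else TRUE
})

#' Construct a hard-mining configuration
#'
#' Defaults are the standard configuration: k = 8 tiles mined per slide,
#' training triggered once 256 mined tiles have accumulated, batches of 32,
#' and the switch to mining after 2 epochs without validation improvement.
#'
#' @param k tiles selected per slide during mining.
#' @param N mined-pool size that triggers a training run.
#' @param batchSize tiles per training batch.
#' @param numLabels number of labels.
#' @param switchPatience epochs without validation improvement before mining.
#' @return a [MiningConfig-class] object.
#' @export
miningConfig <- function(k = 8L, N = 256L, batchSize = 32L, numLabels = 2L,
                         switchPatience = 2L) {
  new("MiningConfig", k = as.integer(k), N = as.integer(N),
      batchSize = as.integer(batchSize), numLabels = as.integer(numLabels),
      switchPatience = as.integer(switchPatience))
}

setMethod("show", "MiningConfig", function(object) {
  cat(sprintf("MiningConfig: k=%d, N=%d, batchSize=%d, numLabels=%d, switchPatience=%d\n",
              object@k, object@N, object@batchSize, object@numLabels,
              object@switchPatience))
})

#' Training configuration
#'
#' Optimizer, schedule and stopping rules. The learning rate at (0-based)
#' epoch e is `lr0 * decayFactor^floor(e / decayEvery)`.
#'
#' @slot lr0 numeric initial learning rate.
#' @slot decayFactor numeric multiplicative decay.
#' @slot decayEvery integer epochs between decays.
#' @slot beta1,beta2 numeric Adam moment decay rates.
#' @slot earlyStopPatience integer epochs without validation improvement
#'   before stopping.
#' @slot maxEpochs integer epoch cap.
#' @slot backbone `"tiny_cnn"` or `"efficientnet_b1"`.
#' @slot finetune `"partial"` (batch-norm affine + head only) or `"full"`.
#' @slot valTilesPerSlide integer size of the fixed per-slide validation
#'   tile sample.
#' @slot seed integer seed for weight init and tile draws.
#' @export
setClass("TrainConfig", representation(
  lr0 = "numeric", decayFactor = "numeric", decayEvery = "integer",
  beta1 = "numeric", beta2 = "numeric", earlyStopPatience = "integer",
  maxEpochs = "integer", backbone = "character", finetune = "character",
  valTilesPerSlide = "integer", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lr0 <= 0) msg <- c(msg, "lr0 must be positive")
  if (object@decayFactor <= 0 || object@decayFactor > 1)
    msg <- c(msg, "decayFactor must be in (0, 1]")
  if (object@decayEvery < 1L) msg <- c(msg, "decayEvery must be >= 1")
  if (object@beta1 < 0 || object@beta1 >= 1 ||
      object@beta2 < 0 || object@beta2 >= 1)
    msg <- c(msg, "beta1/beta2 must be in [0, 1)")
  if (object@earlyStopPatience < 1L) msg <- c(msg, "earlyStopPatience >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs >= 1")
  if (!object@backbone %in% c("tiny_cnn", "efficientnet_b1"))
    msg <- c(msg, "backbone must be 'tiny_cnn' or 'efficientnet_b1'")
  if (!object@finetune %in% c("partial", "full"))
    msg <- c(msg, "finetune must be 'partial' or 'full'")
  if (length(msg)) msg else TRUE
})

#' Construct a training configuration
#'
#' Defaults follow the standard fine-tuning recipe: Adam with beta1 0.9 and
#' beta2 0.999, initial learning rate 0.001 decayed by 0.95 every 2 epochs,
#' binary cross-entropy loss, early stopping after 10 epochs without
#' validation improvement, and partial fine-tuning (only the affine
#' batch-normalization parameters and the classifier head train).
#'
#' @param lr0 initial learning rate.
#' @param decayFactor multiplicative learning-rate decay.
#' @param decayEvery epochs between decays.
#' @param beta1,beta2 Adam moment decay rates.
#' @param earlyStopPatience early-stopping patience in epochs.
#' @param maxEpochs epoch cap.
#' @param backbone backbone family.
#' @param finetune `"partial"` or `"full"`.
#' @param valTilesPerSlide fixed validation tile sample size per slide.
#' @param seed integer seed.
#' @return a [TrainConfig-class] object.
#' @export
trainConfig <- function(lr0 = 0.001, decayFactor = 0.95, decayEvery = 2L,
                        beta1 = 0.9, beta2 = 0.999, earlyStopPatience = 10L,
                        maxEpochs = 100L, backbone = "tiny_cnn",
                        finetune = "partial", valTilesPerSlide = 64L,
                        seed = 1L) {
  new("TrainConfig", lr0 = lr0, decayFactor = decayFactor,
      decayEvery = as.integer(decayEvery), beta1 = beta1, beta2 = beta2,
      earlyStopPatience = as.integer(earlyStopPatience),
      maxEpochs = as.integer(maxEpochs), backbone = backbone,
      finetune = finetune, valTilesPerSlide = as.integer(valTilesPerSlide),
      seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %s (%s fine-tune), lr0=%g x %g every %d epochs, Adam(%.3g, %.4g),\n  early stop %d, max %d epochs, %d val tiles/slide, seed %d\n",
    object@backbone, object@finetune, object@lr0, object@decayFactor,
    object@decayEvery, object@beta1, object@beta2, object@earlyStopPatience,
    object@maxEpochs, object@valTilesPerSlide, object@seed))
})

#' Label-alternating slide queue
#'
#' A shuffled queue over training slides that alternates between emitting a
#' positive-label and a negative-label slide. When one label's list is
#' exhausted before the other's within an epoch, that label is re-drawn
#' uniformly with replacement (oversampling) so alternation continues until
#' the larger list is exhausted; the queue then reshuffles for the next
#' epoch.
#'
#' @slot slideIds character slide identifiers.
#' @slot labels integer 0/1 labels aligned with `slideIds`.
#' @slot posOrder,negOrder integer index permutations for the current epoch.
#' @slot posCursor,negCursor integer cursors into the permutations.
#' @slot nextLabel integer label (0/1) to emit next.
#' @slot epoch integer epoch counter (0-based).
#' @slot draws integer count of random draws made (part of the rng state).
#' @slot seed integer seed.
#' @export
setClass("SlideQueue", representation(
  slideIds = "character", labels = "integer",
  posOrder = "integer", negOrder = "integer",
  posCursor = "integer", negCursor = "integer",
  nextLabel = "integer", epoch = "integer", draws = "integer",
  seed = "integer"
))

setMethod("show", "SlideQueue", function(object) {
  cat(sprintf("SlideQueue: %d slides (%d positive / %d negative), epoch %d\n",
              length(object@slideIds), sum(object@labels == 1L),
              sum(object@labels == 0L), object@epoch))
})

#' Metric report with bootstrap confidence intervals
#'
#' @slot metrics data.frame with columns `metric, estimate, lo, hi`.
#' @slot nBootstrap integer bootstrap iterations.
#' @slot threshold numeric operating threshold for the confusion metrics.
#' @slot seed integer bootstrap seed.
#' @export
setClass("MetricReport", representation(
  metrics = "data.frame", nBootstrap = "integer", threshold = "numeric",
  seed = "integer"
))

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("MetricReport (threshold %.2f, %d bootstrap iterations):\n",
              object@threshold, object@nBootstrap))
  m <- object@metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.4f  (95%% CI %.4f-%.4f)\n",
                m$metric[i], m$estimate[i], m$lo[i], m$hi[i]))
  }
})

#' @describeIn MetricReport-class the metric table.
#' @param x a `MetricReport`.
#' @export
metricTable <- function(x) x@metrics
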