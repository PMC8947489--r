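# Training loop: balanced random sampling, then hard mining, with Adam,
# stepped learning-rate decay, validation-loss tracking, early stopping and
# lowest-validation-loss checkpoint selection.

#' Learning rate at a given epoch
#'
#' `lr0 * decayFactor^floor(e / decayEvery)` with 0-based epoch index: with
#' the defaults, 0.001 at epochs 0-1, 0.00095 at 2-3, 0.0009025 at 4-5, ...
#'
#' @param e 0-based epoch index (vectorized).
#' @param cfg a [TrainConfig-class].
#' @return numeric learning rate(s).
#' @export
lrAtEpoch <- function(e, cfg = trainConfig()) {
  stopifnot(all(e >= 0))
  cfg@lr0 * cfg@decayFactor^floor(e / cfg@decayEvery)
}

bceLoss <- function(probs, y, eps = 1e-7) {
  p <- clip(probs, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Eval-mode probabilities for a (possibly large) prepared tile set, chunked
# to bound the im2col working set.
predictBatched <- function(model, images, tiles, tileSize, batchSize = 32L) {
  n <- nrow(tiles)
  probs <- numeric(n)
  for (start in seq.int(1L, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    data <- extractTileBatch(images, tiles[idx, , drop = FALSE], tileSize)
    probs[idx] <- modelProbs(model, data, tileSize, length(idx))
  }
  probs
}

# Fixed, seeded per-slide validation tile sample (same tiles every epoch).
validationTiles <- function(tilePools, valManifest, perSlide, seed) {
  parts <- lapply(seq_len(nrow(valManifest)), function(i) {
    sid <- valManifest$slide_id[i]
    pool <- tilePools[[sid]]
    if (is.null(pool) || nrow(pool) == 0L) return(NULL)
    ids <- withSeed(deriveSeed(seed, paste0("valtiles/", sid)), {
      sample.int(nrow(pool), min(perSlide, nrow(pool)))
    })
    part <- pool[ids, , drop = FALSE]
    part$label <- asBinaryLabel(valManifest$label[i])
    part
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Validation loss of a model
#'
#' Mean binary cross-entropy over a fixed, seeded per-slide sample of
#' validation tiles, with labels inherited from the slides. The sample is a
#' deterministic function of the seed, so the same tiles are scored every
#' epoch.
#'
#' @param model a `wsiModel`.
#' @param valManifest manifest rows of the validation split.
#' @param tileSize,stride,minTissueFrac tile-grid settings.
#' @param valTilesPerSlide per-slide sample size.
#' @param seed integer seed for the tile sample.
#' @return scalar loss.
#' @export
validationLoss <- function(model, valManifest, tileSize, stride = tileSize,
                           minTissueFrac = 0.1, valTilesPerSlide = 64L,
                           seed = 1L) {
  images <- loadSlideImages(valManifest)
  pools <- buildTilePools(images, valManifest, tileSize, stride, minTissueFrac)
  tiles <- validationTiles(pools, valManifest, valTilesPerSlide, seed)
  probs <- predictBatched(model, images, tiles, tileSize)
  bceLoss(probs, tiles$label)
}

loadSlideImages <- function(manifest) {
  images <- lapply(manifest$image_path, function(p) {
    img <- readSlideImage(p)
    if (length(dim(img)) == 3L) toGrayscale(img) else img
  })
  names(images) <- manifest$slide_id
  images
}

buildTilePools <- function(images, manifest, tileSize, stride, minTissueFrac) {
  pools <- lapply(seq_along(images), function(i) {
    tm <- buildTissueMask(images[[i]])
    tileGrid(tm, tileSize, stride, minTissueFrac,
             slideId = manifest$slide_id[i])
  })
  names(pools) <- manifest$slide_id
  pools
}

#' Train a weakly supervised slide classifier
#'
#' Runs the two-phase training loop on slide-level labels only: balanced
#' random tile sampling from a label-alternating slide queue until the
#' validation loss stalls for `switchPatience` epochs, then hard-example
#' mining (full-grid inference per slide with frozen weights, selection of
#' the k most label-inconsistent tiles, training triggered whenever N mined
#' tiles have accumulated). Training stops when the validation loss has not
#' improved for `earlyStopPatience` epochs or at `maxEpochs`; the checkpoint
#' with the lowest validation loss is returned. Lesion masks are never read.
#'
#' @param manifest cohort manifest with train and validation splits.
#' @param cfg a [TrainConfig-class].
#' @param mining a [MiningConfig-class].
#' @param tileSize tile side in pixels.
#' @param stride tile-grid stride (default `tileSize`).
#' @param minTissueFrac minimum per-tile tissue fraction.
#' @param evaluator optional `function(model, epoch)` returning the
#'   validation loss; defaults to the fixed-tile-sample evaluator. Intended
#'   for tests and callbacks.
#' @param epochHook optional `function(model, epoch, valLoss)` called after
#'   each epoch's evaluation.
#' @param outDir optional directory for a JSON-lines training log and the
#'   final checkpoint.
#' @param verbose print per-epoch progress.
#' @return a `wsiFit` list: `model` (best checkpoint), `history` (one row
#'   per epoch: epoch, phase, lr, train_loss, val_loss), `bestEpoch`,
#'   `bestValLoss`, `phase`, `trainable`.
#' @export
fit <- function(manifest, cfg = trainConfig(), mining = miningConfig(),
                tileSize = 128L, stride = tileSize, minTissueFrac = 0.1,
                evaluator = NULL, epochHook = NULL, outDir = NULL,
                verbose = FALSE) {
  trainM <- manifest[manifest$split == "train", , drop = FALSE]
  valM <- manifest[manifest$split == "validation", , drop = FALSE]
  if (nrow(valM) == 0L)
    stop("empty validation split: both the mining switch and early stopping depend on it")
  if (length(unique(asBinaryLabel(trainM$label))) < 2L)
    stop("training split must contain both labels")

  images <- loadSlideImages(trainM)
  pools <- buildTilePools(images, trainM, tileSize, stride, minTissueFrac)
  if (is.null(evaluator)) {
    valImages <- loadSlideImages(valM)
    valPools <- buildTilePools(valImages, valM, tileSize, stride, minTissueFrac)
    valTiles <- validationTiles(valPools, valM, cfg@valTilesPerSlide, cfg@seed)
    evaluator <- function(model, epoch) {
      bceLoss(predictBatched(model, valImages, valTiles, tileSize,
                             mining@batchSize), valTiles$label)
    }
  }

  model <- createBackbone(cfg@backbone, inputChannels = 1L, seed = cfg@seed)
  trainable <- trainableParameterMask(model, cfg@finetune)
  optState <- adamInit(model$params)
  queue <- buildQueue(trainM, seed = deriveSeed(cfg@seed, "queue"))
  labelsBin <- asBinaryLabel(trainM$label)
  nPairs <- max(sum(labelsBin == 1L), sum(labelsBin == 0L))

  phase <- "random_sampling"
  valHist <- numeric(0)
  hist <- list()
  bestModel <- NULL; bestEpoch <- NA_integer_; bestVal <- Inf
  pool <- NULL
  logCon <- if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    file.path(outDir, "training_log.jsonl")
  } else NULL

  for (e in 0:(cfg@maxEpochs - 1L)) {
    lr <- lrAtEpoch(e, cfg)
    losses <- numeric(0)
    if (phase == "random_sampling") {
      for (i in seq_len(nPairs)) {
        sb <- sampleBalancedBatch(queue, pools, mining,
                                  seed = deriveSeed(cfg@seed,
                                                    paste0("batch", e, "_", i)))
        queue <- sb$queue
        st <- trainStep(model, optState, images, sb$batch, sb$batch$label,
                        tileSize, lr, cfg, trainable)
        model <- st$model; optState <- st$optState
        losses <- c(losses, st$loss)
      }
      queue <- reshuffleQueue(queue)
    } else {
      # hard mining: full-grid inference per slide (weights frozen), then
      # FIFO-released training runs of N tiles in batchSize chunks
      ep <- epochSlides(queue)
      queue <- ep$queue
      for (i in seq_len(nrow(ep$slides))) {
        sid <- ep$slides$slide_id[i]
        grid <- pools[[sid]]
        if (is.null(grid) || nrow(grid) == 0L) next
        probs <- predictBatched(model, images, grid, tileSize,
                                mining@batchSize)
        pmap <- new("TileProbabilityMap", slideId = sid,
                    tileSize = as.integer(tileSize),
                    stride = as.integer(stride),
                    tiles = cbind(grid, prob = probs))
        sel <- selectHardTiles(pmap, ep$slides$label[i], mining@k)
        sel$label <- ep$slides$label[i]
        sel$prob <- NULL
        upd <- miningPoolUpdate(pool, sel, mining@N)
        pool <- upd$pool
        if (upd$ready) {
          rel <- upd$released
          for (start in seq.int(1L, nrow(rel), by = mining@batchSize)) {
            chunk <- rel[start:min(start + mining@batchSize - 1L, nrow(rel)), ,
                         drop = FALSE]
            st <- trainStep(model, optState, images, chunk, chunk$label,
                            tileSize, lr, cfg, trainable)
            model <- st$model; optState <- st$optState
            losses <- c(losses, st$loss)
          }
        }
      }
    }

    valLoss <- evaluator(model, e)
    valHist <- c(valHist, valLoss)
    if (valLoss < bestVal) {
      bestVal <- valLoss; bestEpoch <- e; bestModel <- model
    }
    hist[[e + 1L]] <- data.frame(epoch = e, phase = phase, lr = lr,
                                 train_loss = if (length(losses)) mean(losses) else NA_real_,
                                 val_loss = valLoss)
    if (!is.null(epochHook)) epochHook(model, e, valLoss)
    if (!is.null(logCon)) {
      cat(jsonlite::toJSON(hist[[e + 1L]], auto_unbox = TRUE, digits = NA),
          "\n", sep = "", file = logCon, append = TRUE)
    }
    if (!is.null(outDir) && phase == "hard_mining") {
      # mining state snapshot: pending pool as a tile TSV plus a JSON cursor
      poolPath <- file.path(outDir, "mining_pool.tsv")
      if (!is.null(pool) && nrow(pool)) writeTilesTSV(pool, poolPath)
      jsonlite::write_json(
        list(epoch = e, phase = phase,
             pool_size = if (is.null(pool)) 0L else nrow(pool),
             pool_tsv = if (!is.null(pool) && nrow(pool)) basename(poolPath)
                        else NULL),
        file.path(outDir, "mining_state.json"), auto_unbox = TRUE,
        digits = NA, null = "null")
    }
    if (verbose)
      message(sprintf("epoch %d [%s] lr=%.3g train=%.4f val=%.4f", e, phase,
                      lr, hist[[e + 1L]]$train_loss, valLoss))

    # phase transition fires once, never back
    if (phase == "random_sampling" &&
        shouldSwitchToMining(valHist, mining@switchPatience)) {
      phase <- "hard_mining"
    }
    if ((e - bestEpoch) >= cfg@earlyStopPatience) break
  }

  res <- structure(list(model = bestModel,
                        history = do.call(rbind, hist),
                        bestEpoch = bestEpoch, bestValLoss = bestVal,
                        phase = phase, trainable = trainable),
                   class = "wsiFit")
  if (!is.null(outDir)) {
    saveRDS(bestModel, file.path(outDir, "checkpoint.rds"))
    jsonlite::write_json(
      list(best_epoch = bestEpoch, best_val_loss = bestVal,
           phase = phase, backbone = cfg@backbone, finetune = cfg@finetune),
      file.path(outDir, "checkpoint.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.wsiFit <- function(x, ...) {
  cat(sprintf(
    "wsiFit: %d epochs, best validation loss %.4f at epoch %d, final phase '%s'\n",
    nrow(x$history), x$bestValLoss, x$bestEpoch, x$phase))
  invisible(x)
}
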