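# Balanced slide queue, balanced tile batches, and hard-example mining.
#
# Training supervision is weak: tiles inherit their slide's label, and the
# sampler consumes only the manifest columns that carry no lesion locations.

#' Build a label-alternating slide queue
#'
#' Slides of each label are placed in a seeded shuffled order; emission
#' alternates between the two labels (starting label is part of the seeded
#' shuffle). When one label runs out before the other within an epoch, it
#' is re-drawn uniformly with replacement (oversampling) until the larger
#' list is exhausted, at which point the epoch ends and the queue
#' reshuffles.
#'
#' @param manifest data.frame with `slide_id` and `label` columns.
#' @param seed integer seed.
#' @return a [SlideQueue-class] object.
#' @export
buildQueue <- function(manifest, seed = 1L) {
  labels <- asBinaryLabel(manifest$label)
  if (length(unique(labels)) < 2L)
    stop("queue needs at least one slide of each label")
  q <- new("SlideQueue", slideIds = as.character(manifest$slide_id),
           labels = labels, posOrder = integer(0), negOrder = integer(0),
           posCursor = 0L, negCursor = 0L, nextLabel = 0L, epoch = -1L,
           draws = 0L, seed = as.integer(seed))
  reshuffleQueue(q)
}

reshuffleQueue <- function(q) {
  q@epoch <- q@epoch + 1L
  pos <- which(q@labels == 1L); neg <- which(q@labels == 0L)
  withSeed(deriveSeed(q@seed, paste0("epoch", q@epoch)), {
    q@posOrder <- pos[sample.int(length(pos))]
    q@negOrder <- neg[sample.int(length(neg))]
    q@nextLabel <- sample(c(0L, 1L), 1L)
  })
  q@posCursor <- 0L
  q@negCursor <- 0L
  q
}

#' Draw the next slide from the queue
#'
#' @param q a [SlideQueue-class].
#' @return list with elements `queue` (updated), `slideId`, `label`,
#'   `oversampled` (TRUE when the slide was re-drawn with replacement), and
#'   `epochEnded` (TRUE when this draw completed the epoch).
#' @export
queueNext <- function(q) {
  lab <- q@nextLabel
  ord <- if (lab == 1L) q@posOrder else q@negOrder
  cur <- if (lab == 1L) q@posCursor else q@negCursor
  oversampled <- FALSE
  if (cur < length(ord)) {
    cur <- cur + 1L
    idx <- ord[cur]
    if (lab == 1L) q@posCursor <- cur else q@negCursor <- cur
  } else {
    # this label is exhausted: oversample uniformly with replacement
    q@draws <- q@draws + 1L
    idx <- withSeed(deriveSeed(q@seed, paste0("draw", q@epoch, "_", q@draws)),
                    ord[sample.int(length(ord), 1L)])
    oversampled <- TRUE
  }
  q@nextLabel <- 1L - lab
  epochEnded <- q@posCursor >= length(q@posOrder) &&
                q@negCursor >= length(q@negOrder)
  list(slideId = q@slideIds[idx], label = q@labels[idx],
       oversampled = oversampled, epochEnded = epochEnded, queue = q)
}

#' Emit one full epoch of label-alternating slide draws
#'
#' Draws `2 * max(n_pos, n_neg)` slides so that the larger label list is
#' traversed exactly once and the smaller is oversampled to keep the
#' alternation, then reshuffles for the next epoch. Every training slide
#' appears at least once per epoch.
#'
#' @param q a [SlideQueue-class].
#' @return list with `slides` (data.frame `slide_id`, `label`,
#'   `oversampled`) and the reshuffled `queue`.
#' @export
epochSlides <- function(q) {
  nPairs <- max(sum(q@labels == 1L), sum(q@labels == 0L))
  rows <- vector("list", 2L * nPairs)
  for (i in seq_len(2L * nPairs)) {
    nx <- queueNext(q)
    q <- nx$queue
    rows[[i]] <- data.frame(slide_id = nx$slideId, label = nx$label,
                            oversampled = nx$oversampled,
                            stringsAsFactors = FALSE)
  }
  list(slides = do.call(rbind, rows), queue = reshuffleQueue(q))
}

#' Sample one balanced tile batch
#'
#' Draws one slide per label from the queue and `batchSize / numLabels`
#' tiles uniformly from each slide's tile pool (without replacement when the
#' pool is large enough, with replacement -- oversampling -- otherwise), so
#' every batch is exactly label-balanced. Slides whose pool is empty are
#' skipped with a warning and another slide of the same label is drawn.
#'
#' @param q a [SlideQueue-class].
#' @param tilePools named list (by slide id) of tile data.frames from
#'   [tileGrid()].
#' @param cfg a [MiningConfig-class].
#' @param seed integer seed for the tile draws.
#' @return list with `batch` (data.frame of tile rows plus `label`) and the
#'   updated `queue`.
#' @export
sampleBalancedBatch <- function(q, tilePools, cfg = miningConfig(),
                                seed = 1L) {
  perSlide <- cfg@batchSize %/% cfg@numLabels
  parts <- vector("list", cfg@numLabels)
  for (j in seq_len(cfg@numLabels)) {
    attempts <- 0L
    repeat {
      nx <- queueNext(q); q <- nx$queue
      pool <- tilePools[[nx$slideId]]
      if (!is.null(pool) && nrow(pool) > 0L) break
      warning("slide ", nx$slideId, " has an empty tile pool; skipped")
      # re-draw the same label until a usable slide appears
      q@nextLabel <- nx$label
      attempts <- attempts + 1L
      if (attempts > 2L * length(q@slideIds))
        stop("all tile pools of label ", nx$label, " are empty")
    }
    n <- nrow(pool)
    ids <- withSeed(deriveSeed(seed, paste0("tiles/", nx$slideId, "/",
                                            q@epoch, "/", q@draws, "/",
                                            q@posCursor, "/", q@negCursor)), {
      if (n >= perSlide) sample.int(n, perSlide)
      else sample.int(n, perSlide, replace = TRUE)
    })
    part <- pool[ids, , drop = FALSE]
    part$label <- nx$label
    parts[[j]] <- part
  }
  batch <- do.call(rbind, parts)
  rownames(batch) <- NULL
  list(batch = batch, queue = q)
}

#' Select the hard tiles of one slide
#'
#' For a negative slide, the k tiles with the highest positive-class
#' probability; for a positive slide, the k tiles with the lowest. These are
#' the tiles most inconsistent with the slide label, i.e. the examples the
#' model is struggling with. Ties are broken by row-major tile order
#' (y, then x); if fewer than k tiles exist, all are returned.
#'
#' @param tileProbMap a [TileProbabilityMap-class].
#' @param slideLabel slide label (binary; see [asBinaryLabel()]).
#' @param k number of tiles to select.
#' @return data.frame of the selected tile rows, in selection order.
#' @export
selectHardTiles <- function(tileProbMap, slideLabel, k) {
  tiles <- tileProbs(tileProbMap)
  if (nrow(tiles) == 0L) stop("empty tile probability map")
  y <- asBinaryLabel(slideLabel)
  ord <- if (y == 0L) order(-tiles$prob, tiles$y, tiles$x)
         else        order(tiles$prob, tiles$y, tiles$x)
  out <- tiles[ord[seq_len(min(k, nrow(tiles)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decide whether to switch from random sampling to hard mining
#'
#' TRUE once the running minimum of the validation loss has not strictly
#' decreased within the last `patience` completed epochs.
#'
#' @param valLossHistory numeric vector of per-epoch validation losses.
#' @param patience integer number of stale epochs that triggers the switch.
#' @return logical.
#' @export
shouldSwitchToMining <- function(valLossHistory, patience = 2L) {
  stopifnot(length(valLossHistory) >= 1L)
  best <- which.min(valLossHistory)  # first occurrence: later equal values
                                     # are not an improvement
  (length(valLossHistory) - best) >= patience
}

#' Update the hard-mining tile pool
#'
#' Appends the newly selected tiles to the accumulating pool; once the pool
#' holds at least N tiles, the oldest N are released FIFO for a training
#' run and removed.
#'
#' @param pool data.frame of accumulated tiles (possibly empty or NULL).
#' @param selected data.frame of newly mined tiles.
#' @param N release threshold.
#' @return list with `pool` (remaining tiles), `released` (exactly N tiles
#'   or NULL), and `ready` (logical).
#' @export
miningPoolUpdate <- function(pool, selected, N) {
  pool <- if (is.null(pool) || nrow(pool) == 0L) selected
          else rbind(pool, selected)
  if (!is.null(pool)) rownames(pool) <- NULL
  if (!is.null(pool) && nrow(pool) >= N) {
    list(pool = pool[-seq_len(N), , drop = FALSE],
         released = pool[seq_len(N), , drop = FALSE], ready = TRUE)
  } else {
    list(pool = pool, released = NULL, ready = FALSE)
  }
}
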