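# Sliding-window tile prediction, max-aggregated slide scoring, and
# jet-colormap heatmap rendering.

#' Predict tile probabilities over a slide
#'
#' Applies the model to every tile of the grid in eval mode (batch-norm
#' running statistics), so the probabilities are independent of how tiles
#' are batched.
#'
#' @param model a `wsiModel`.
#' @param image the slide image (gray matrix or RGB array, 0..255).
#' @param grid data.frame of tiles from [tileGrid()].
#' @param batchSize tiles per forward pass.
#' @param stride grid stride recorded in the result.
#' @return a [TileProbabilityMap-class].
#' @export
predictTiles <- function(model, image, grid, batchSize = 32L,
                         stride = NULL) {
  if (is.null(grid) || nrow(grid) == 0L)
    stop("no tissue detected: empty tile grid")
  tileSize <- grid$tile_size[1]
  gray <- if (length(dim(image)) == 3L) toGrayscale(image) else image
  probs <- predictBatched(model, gray, grid, tileSize, batchSize)
  new("TileProbabilityMap",
      slideId = as.character(grid$slide_id[1]),
      tileSize = as.integer(tileSize),
      stride = as.integer(if (is.null(stride)) tileSize else stride),
      tiles = cbind(grid, prob = probs))
}

#' Max-aggregated slide score
#'
#' The slide-level prediction is the maximum over its tile probabilities: a
#' positive slide needs only one confidently positive tile.
#'
#' @param map a [TileProbabilityMap-class].
#' @return scalar probability.
#' @export
slideScore <- function(map) {
  tiles <- tileProbs(map)
  if (nrow(tiles) == 0L) stop("empty tile probability map")
  max(tiles$prob)
}

#' Evaluate the jet colormap
#'
#' The standard piecewise-linear blue-cyan-yellow-red map, fixed in code:
#' each channel is `clamp(1.5 - |4p - c|)` with centers 3 (red), 2 (green),
#' 1 (blue). p = 0 renders blue, p = 1 renders red.
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return matrix with columns r, g, b in \[0, 1\].
#' @export
jetColor <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cbind(r = clip(1.5 - abs(4 * p - 3), 0, 1),
        g = clip(1.5 - abs(4 * p - 2), 0, 1),
        b = clip(1.5 - abs(4 * p - 1), 0, 1))
}

#' Render a probability heatmap over the slide
#'
#' Each tile footprint is colored by the jet colormap at its probability and
#' alpha-blended over the slide; where tiles overlap (stride < tile size)
#' their probabilities are averaged for display. Pixels outside every tile
#' footprint are left untouched, and `alpha = 0` returns the original image.
#'
#' @param map a [TileProbabilityMap-class].
#' @param image the slide image the map was computed on.
#' @param alpha blend fraction in \[0, 1\].
#' @param path optional output PNG path.
#' @return H x W x 3 numeric array in \[0, 1\] (written to `path` if given),
#'   invisibly when `path` is set.
#' @export
renderHeatmap <- function(map, image, alpha = 0.5, path = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  tiles <- tileProbs(map)
  tsz <- map@tileSize
  gray <- if (length(dim(image)) == 3L) image else
    array(rep(image, 3) / 1, dim = c(dim(image), 3))
  h <- dim(gray)[1]; w <- dim(gray)[2]
  if (nrow(tiles) &&
      (max(tiles$x) + tsz > w || max(tiles$y) + tsz > h ||
       min(tiles$x) < 0 || min(tiles$y) < 0))
    stop("tile map is misaligned with the image geometry")
  psum <- matrix(0, h, w); pcnt <- matrix(0, h, w)
  for (i in seq_len(nrow(tiles))) {
    ry <- (tiles$y[i] + 1L):(tiles$y[i] + tsz)
    rx <- (tiles$x[i] + 1L):(tiles$x[i] + tsz)
    psum[ry, rx] <- psum[ry, rx] + tiles$prob[i]
    pcnt[ry, rx] <- pcnt[ry, rx] + 1
  }
  covered <- pcnt > 0
  out <- gray / 255
  if (any(covered) && alpha > 0) {
    pavg <- psum[covered] / pcnt[covered]
    colr <- jetColor(pavg)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[covered] <- (1 - alpha) * plane[covered] + alpha * colr[, ch]
      out[, , ch] <- plane
    }
  }
  if (!is.null(path)) {
    png::writePNG(out, target = path)
    return(invisible(out))
  }
  out
}

#' Score every slide of a manifest split
#'
#' Builds each slide's tissue mask and tile grid, predicts tile
#' probabilities, and aggregates by maximum, yielding a scored cohort.
#'
#' @param model a `wsiModel`.
#' @param manifest manifest rows to score.
#' @param tileSize,stride,minTissueFrac tile-grid settings.
#' @param batchSize tiles per forward pass.
#' @param mapsDir optional directory: per-slide prediction TSVs
#'   (`slide_id, x, y, tile_size, prob`) are written there.
#' @return data.frame `slide_id, label, score` (the scored cohort), with
#'   the tile maps as the `"maps"` attribute.
#' @export
scoreCohort <- function(model, manifest, tileSize, stride = tileSize,
                        minTissueFrac = 0.1, batchSize = 32L,
                        mapsDir = NULL) {
  maps <- vector("list", nrow(manifest))
  scores <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- readSlideImage(manifest$image_path[i])
    tm <- buildTissueMask(img)
    grid <- tileGrid(tm, tileSize, stride, minTissueFrac,
                     slideId = manifest$slide_id[i])
    map <- predictTiles(model, img, grid, batchSize, stride)
    maps[[i]] <- map
    scores[i] <- slideScore(map)
    if (!is.null(mapsDir)) {
      dir.create(mapsDir, showWarnings = FALSE, recursive = TRUE)
      tp <- tileProbs(map)
      utils::write.table(
        data.frame(slide_id = manifest$slide_id[i], x = tp$x, y = tp$y,
                   tile_size = tp$tile_size, prob = tp$prob),
        file.path(mapsDir, paste0(manifest$slide_id[i], "_predictions.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out <- data.frame(slide_id = manifest$slide_id, label = manifest$label,
                    score = scores, stringsAsFactors = FALSE)
  names(maps) <- manifest$slide_id
  attr(out, "maps") <- maps
  out
}
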