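# Tissue detection and tile-grid enumeration.
#
# Tissue is separated from the near-white slide background by Otsu
# thresholding on a grayscale version of the image: tissue = gray strictly
# below the threshold. Tiles are enumerated on a fixed grid in raster order
# (0-based origins, x right / y down, half-open [x, x+T) x [y, y+T)).

#' Convert an 8-bit image to grayscale
#'
#' RGB images are converted with the ITU-R 601 luminance weights
#' 0.299 / 0.587 / 0.114 and rounded; grayscale input is returned unchanged.
#'
#' @param image integer matrix (gray) or H x W x 3 array (RGB), values 0..255.
#' @return integer matrix of gray values 0..255.
#' @export
toGrayscale <- function(image) {
  if (!is.numeric(image) || any(image < 0 | image > 255) ||
      any(image != floor(image)))
    stop("toGrayscale expects an 8-bit image with integer values in 0..255")
  if (length(dim(image)) == 2L) {
    return(matrix(as.integer(image), nrow = nrow(image)))
  }
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected a gray matrix or an H x W x 3 RGB array")
  g <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  matrix(as.integer(g), nrow = dim(image)[1])
}

#' Otsu threshold of a gray image
#'
#' Chooses the 8-bit level that maximizes the between-class variance of the
#' 256-bin histogram split into \{gray < t\} versus \{gray >= t\},
#' scanning every candidate t; ties are broken by the lowest threshold.
#'
#' @param gray integer matrix of gray values 0..255 with at least two
#'   distinct levels.
#' @return integer threshold t in 1..255; tissue is `gray < t`.
#' @export
otsuThreshold <- function(gray) {
  g <- as.integer(gray)
  if (any(g < 0L | g > 255L)) stop("gray values must be in 0..255")
  counts <- tabulate(g + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct gray levels")
  n <- sum(counts)
  p <- counts / n
  levels <- 0:255
  # class 0 = {gray < t} for t = 1..255
  w0 <- cumsum(p)[1:255]
  mu0 <- cumsum(p * levels)[1:255]
  muT <- sum(p * levels)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (muT * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  as.integer(which.max(bcv))  # which.max takes the first (lowest) maximizer
}

#' Build the tissue mask of a slide image
#'
#' Converts to grayscale, computes the Otsu threshold, and marks every pixel
#' strictly below it as tissue. Beyond an optional small-object removal, no
#' morphological cleanup is applied.
#'
#' @param image 8-bit image (gray matrix or RGB array).
#' @param minObjectSize if positive, connected tissue components (4-neighbor)
#'   smaller than this many pixels are dropped.
#' @return a [TissueMask-class] object.
#' @export
buildTissueMask <- function(image, minObjectSize = 0L) {
  gray <- toGrayscale(image)
  t <- otsuThreshold(gray)
  mask <- gray < t
  if (minObjectSize > 0L) mask <- removeSmallObjects(mask, minObjectSize)
  new("TissueMask", mask = mask, threshold = t,
      sourceSize = as.integer(dim(gray)))
}

# Drop 4-connected components smaller than minSize (union-find-free
# iterative flood fill via column-wise run labelling).
removeSmallObjects <- function(mask, minSize) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(mask)
  keep <- which(tabulate(lab[lab > 0L]) >= minSize)
  mask & matrix(lab %in% keep, nrow = nrow(mask))
}

# 4-connected component labelling with a two-pass union-find over
# column runs; adequate for slide-scale masks.
labelComponents <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nextLab <- 0L
  for (x in seq_len(w)) {
    col <- mask[, x]
    if (!any(col)) next
    r <- rle(col)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      nextLab <- nextLab + 1L
      parent[nextLab] <- nextLab
      lab[starts[k]:ends[k], x] <- nextLab
      if (x > 1L) {
        left <- unique(lab[starts[k]:ends[k], x - 1L])
        for (l in left[left > 0L]) {
          ra <- findRoot(l); rb <- findRoot(nextLab)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  if (nextLab == 0L) return(lab)
  roots <- vapply(seq_len(nextLab), findRoot, integer(1))
  compact <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- compact[lab[lab > 0L]]
  lab
}

#' Enumerate the tile grid over tissue
#'
#' Tiles of side `tileSize` are placed at origins `x = i * stride`,
#' `y = j * stride` (0-based) wherever the tile lies fully within the image,
#' in row-major order (y outer, x inner), and emitted when their tissue
#' fraction reaches `minTissueFrac`.
#'
#' @param tmask a [TissueMask-class].
#' @param tileSize tile side in pixels.
#' @param stride grid stride in pixels (default `tileSize`: non-overlapping).
#' @param minTissueFrac minimum tissue fraction for a tile to be emitted.
#' @param slideId slide identifier recorded in the output.
#' @return data.frame with columns `slide_id, x, y, tile_size,
#'   tissue_fraction`.
#' @export
tileGrid <- function(tmask, tileSize, stride = tileSize, minTissueFrac = 0.1,
                     slideId = "slide") {
  stopifnot(is(tmask, "TissueMask"), stride >= 1L)
  h <- tmask@sourceSize[1]; w <- tmask@sourceSize[2]
  if (tileSize > h || tileSize > w)
    stop("tileSize exceeds image side (", h, " x ", w, ")")
  xs <- seq.int(0L, w - tileSize, by = stride)
  ys <- seq.int(0L, h - tileSize, by = stride)
  # summed-area table for O(1) per-tile tissue counts
  sat <- matrix(0, h + 1L, w + 1L)
  sat[-1L, -1L] <- t(apply(apply(tmask@mask, 2, cumsum), 1, cumsum))
  grid <- expand.grid(x = xs, y = ys)  # x varies fastest: row-major
  y1 <- grid$y + 1L; y2 <- grid$y + tileSize + 1L
  x1 <- grid$x + 1L; x2 <- grid$x + tileSize + 1L
  frac <- (sat[cbind(y2, x2)] - sat[cbind(y1, x2)] -
           sat[cbind(y2, x1)] + sat[cbind(y1, x1)]) / tileSize^2
  # a tile must intersect tissue at all, and meet the configured minimum
  keep <- frac > 0 & frac >= minTissueFrac
  n <- sum(keep)
  out <- data.frame(slide_id = rep(slideId, n),
                    x = as.integer(grid$x[keep]),
                    y = as.integer(grid$y[keep]),
                    tile_size = rep(as.integer(tileSize), n),
                    tissue_fraction = frac[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
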