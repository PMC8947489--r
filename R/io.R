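#' Read a slide image as an 8-bit array
#'
#' Reads a single-resolution PNG (or TIFF, if the tiff package is installed)
#' into an integer matrix (grayscale) or H x W x 3 array (RGB) with values
#' in 0..255. Pyramidal formats are out of scope.
#'
#' @param path file path to a .png/.tif/.tiff image.
#' @return integer matrix (gray) or array (RGB), values 0..255.
#' @export
readSlideImage <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(img)[3] == 1L) img <- img[, , 1L]
  }
  out <- array(as.integer(round(img * 255)), dim = dim(img))
  if (length(dim(out)) == 2L) out <- matrix(as.integer(out), nrow = nrow(img))
  out
}

#' Write an 8-bit image to PNG
#'
#' @param img integer matrix (gray) or H x W x 3 array (RGB), values 0..255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSlideImage <- function(img, path) {
  stopifnot(all(img >= 0 & img <= 255))
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# Binary masks travel as single-channel PNGs with 255 = foreground.
readMaskImage <- function(path) {
  m <- readSlideImage(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m >= 128L
}

writeMaskImage <- function(mask, path) {
  writeSlideImage(matrix(as.integer(mask) * 255L, nrow = nrow(mask)), path)
}

manifestColumns <- c("slide_id", "image_path", "label", "magnification",
                     "split", "lesion_mask_path")

#' Read or write a cohort manifest
#'
#' The manifest is a CSV with columns `slide_id, image_path, label,
#' magnification, split, lesion_mask_path`. The lesion mask column is ground
#' truth for evaluation only; the training pipeline never reads it.
#'
#' @param path CSV path.
#' @return data.frame with the manifest columns.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(manifestColumns, names(m))
  if (length(missing)) stop("manifest lacks column(s): ",
                            paste(missing, collapse = ", "))
  m
}

#' @rdname readManifest
#' @param manifest data.frame with at least the manifest columns.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest[, manifestColumns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a tile list as TSV
#'
#' Columns: `slide_id, x, y, tile_size, tissue_fraction`. Coordinates are
#' 0-based pixel origins of half-open tiles `[x, x+T) x [y, y+T)`.
#'
#' @param tiles data.frame of tile references.
#' @param path TSV path.
#' @export
writeTilesTSV <- function(tiles, path) {
  utils::write.table(
    tiles[, c("slide_id", "x", "y", "tile_size", "tissue_fraction")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTilesTSV
#' @export
readTilesTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
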