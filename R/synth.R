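# Synthetic whole-slide images with planted lesion textures.
#
# The generator emulates the features downstream stages depend on: a
# near-white background separable by Otsu thresholding, darker tissue laid
# out either as elongated needle-biopsy-like cores or as rounded blob
# (resection-chip-like) pieces, and -- on positive slides -- a connected
# lesion region whose texture differs from benign tissue in its spatial
# correlation length but not in its per-pixel intensity distribution, so
# tile-scale texture learning is required and single-pixel thresholding
# cannot shortcut the task.

# Zero-mean, unit-variance Gaussian-correlated noise field via circular FFT
# convolution with an isotropic Gaussian kernel of the given sigma (pixels).
# The kernel transform depends only on (h, w, sigma) and is cached.
.kernelCache <- new.env(parent = emptyenv())

smoothNoiseField <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), nrow = h)
  if (sigma <= 0.05) return(z)
  key <- paste(h, w, sigma, sep = "/")
  fk <- .kernelCache[[key]]
  if (is.null(fk)) {
    di <- pmin(0:(h - 1), h - (0:(h - 1)))
    dj <- pmin(0:(w - 1), w - (0:(w - 1)))
    fk <- stats::fft(exp(-outer(di^2, dj^2, "+") / (2 * sigma^2)))
    .kernelCache[[key]] <- fk
  }
  sm <- Re(stats::fft(stats::fft(z) * fk, inverse = TRUE)) / (h * w)
  (sm - mean(sm)) / stats::sd(sm)
}

# Exclusive per-core masks (a pixel belongs to the first core drawn on it).
drawCores <- function(h, w, nCores, shape) {
  xmat <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ymat <- matrix(rep(0:(h - 1), times = w), nrow = h)
  taken <- matrix(FALSE, h, w)
  cores <- vector("list", nCores)
  for (i in seq_len(nCores)) {
    cx <- stats::runif(1, 0.2 * w, 0.8 * w)
    cy <- stats::runif(1, 0.15 * h + (i - 1) * 0.7 * h / nCores,
                          0.15 * h + i * 0.7 * h / nCores)
    if (shape == "needle") {
      # long thin rotated rectangle, aspect >= 8:1
      len <- 0.75 * w
      wid <- max(8, round(len / 10))
      th <- stats::runif(1, -pi / 12, pi / 12)  # near-horizontal strips
      u <- (xmat - cx) * cos(th) + (ymat - cy) * sin(th)
      v <- -(xmat - cx) * sin(th) + (ymat - cy) * cos(th)
      m <- abs(u) <= len / 2 & abs(v) <= wid / 2
    } else {
      # blob: union of overlapping discs along a short random walk
      m <- matrix(FALSE, h, w)
      px <- cx; py <- cy
      for (d in seq_len(6L)) {
        r <- stats::runif(1, 0.05, 0.09) * min(h, w)
        m <- m | ((xmat - px)^2 + (ymat - py)^2 <= r^2)
        step <- stats::runif(2, -0.8, 0.8) * r
        px <- clip(px + step[1], 0.1 * w, 0.9 * w)
        py <- clip(py + step[2], 0.1 * h, 0.9 * h)
      }
    }
    m <- m & !taken
    taken <- taken | m
    cores[[i]] <- m
  }
  cores
}

# Connected lesion of `target` pixels grown from a seed inside the largest
# core: nearest-by-distance tissue pixels of that core first, spilling to
# the next-nearest cores only when one core cannot hold the target.
growLesion <- function(cores, target, h, w) {
  sizes <- vapply(cores, sum, numeric(1))
  ord <- order(sizes, decreasing = TRUE)
  first <- cores[[ord[1]]]
  idx1 <- which(first)
  seedIdx <- idx1[sample.int(length(idx1), 1L)]
  sy <- (seedIdx - 1L) %% h; sx <- (seedIdx - 1L) %/% h
  lesion <- matrix(FALSE, h, w)
  centroid <- function(m) {
    i <- which(m); c(mean((i - 1L) %/% h), mean((i - 1L) %% h))
  }
  cdist <- vapply(cores[ord], function(m) {
    ce <- centroid(m); sqrt((ce[1] - sx)^2 + (ce[2] - sy)^2)
  }, numeric(1))
  fillOrder <- ord[order(c(0, cdist[-1] + 1))]  # seed core first, then nearest
  remaining <- target
  for (ci in fillOrder) {
    if (remaining <= 0L) break
    idx <- which(cores[[ci]])
    if (!length(idx)) next
    py <- (idx - 1L) %% h; px <- (idx - 1L) %/% h
    d2 <- (px - sx)^2 + (py - sy)^2
    take <- idx[order(d2)][seq_len(min(remaining, length(idx)))]
    lesion[take] <- TRUE
    remaining <- remaining - length(take)
  }
  lesion
}

#' Generate one synthetic slide
#'
#' Writes a grayscale PNG slide image together with its ground-truth tissue
#' and lesion masks, and returns a one-row manifest record. On positive
#' slides a connected lesion region with a shorter texture correlation
#' length occupies approximately `lesionFraction` of the tissue area; benign
#' and lesion tissue share the same mean gray level and marginal variance.
#' The lesion mask is ground truth for evaluation only and is never read by
#' the training pipeline (weak supervision).
#'
#' @param params a [SynthParams-class] object. `lesionFraction` must be 0
#'   for benign slides and positive for adenocarcinoma slides.
#' @param label `"adenocarcinoma"` or `"benign"`.
#' @param dir output directory (created if needed).
#' @param slideId slide identifier; used in file names.
#' @param magnification `"20x"` (full resolution) or `"10x"` (half linear
#'   resolution; nominal metadata otherwise).
#' @param split `"train"`, `"validation"` or `"test"`.
#' @return one-row data.frame with the manifest columns plus
#'   `tissue_mask_path`.
#' @export
generateSlide <- function(params, label = c("benign", "adenocarcinoma"),
                          dir = tempdir(), slideId = "slide_0001",
                          magnification = c("20x", "10x"),
                          split = c("train", "validation", "test")) {
  stopifnot(is(params, "SynthParams"))
  validObject(params)
  label <- match.arg(label)
  magnification <- match.arg(magnification)
  split <- match.arg(split)
  if (label == "benign" && params@lesionFraction > 0)
    stop("inconsistent request: lesionFraction > 0 with a benign label")
  if (label == "adenocarcinoma" && params@lesionFraction == 0)
    stop("inconsistent request: adenocarcinoma label with lesionFraction = 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  n <- if (magnification == "10x") params@imageSize %/% 2L else params@imageSize
  h <- n; w <- n
  bg <- params@backgroundLevel
  gB <- bg - 100L          # tissue mean gray; well below bg - textureContrast
  texSd <- 15              # marginal sd shared by benign and lesion texture
  sigmaB <- 3              # benign correlation length (px)
  sigmaL <- sigmaB * exp(-params@textureContrast / 50)

  img <- withSeed(deriveSeed(params@seed, paste0(slideId, "/image")), {
    cores <- drawCores(h, w, params@nCores, params@coreShape)
    tissue <- Reduce(`|`, cores)
    lesion <- matrix(FALSE, h, w)
    if (params@lesionFraction > 0) {
      target <- round(params@lesionFraction * sum(tissue))
      if (target > 0L) lesion <- growLesion(cores, target, h, w)
    }
    benignTex <- gB + texSd * smoothNoiseField(h, w, sigmaB)
    canvas <- matrix(bg + 1.5 * stats::rnorm(h * w), nrow = h)
    canvas[tissue] <- benignTex[tissue]
    if (any(lesion)) {
      lesionTex <- gB + texSd * smoothNoiseField(h, w, sigmaL)
      canvas[lesion] <- lesionTex[lesion]
    }
    list(img = matrix(as.integer(clip(round(canvas), 0, 255)), nrow = h),
         tissue = tissue, lesion = lesion)
  })

  imagePath <- file.path(dir, paste0(slideId, ".png"))
  tissuePath <- file.path(dir, paste0(slideId, "_tissue.png"))
  lesionPath <- file.path(dir, paste0(slideId, "_lesion.png"))
  writeSlideImage(img$img, imagePath)
  writeMaskImage(img$tissue, tissuePath)
  writeMaskImage(img$lesion, lesionPath)

  data.frame(slide_id = slideId, image_path = imagePath, label = label,
             magnification = magnification, split = split,
             lesion_mask_path = lesionPath, tissue_mask_path = tissuePath,
             stringsAsFactors = FALSE)
}

# Largest-remainder apportionment of n slides across split fractions.
roundSplit <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  zeroed <- fractions > 0 & base == 0
  if (any(zeroed))
    warning("split(s) ", paste(names(fractions)[zeroed], collapse = ", "),
            " received 0 slides at n = ", n,
            " (largest-remainder rounding)")
  as.integer(base)
}

#' Generate a cohort of synthetic slides with a manifest
#'
#' Generates `nPos` adenocarcinoma and `nNeg` benign slides, assigns each
#' label's slides to train/validation/test splits by largest-remainder
#' rounding of `splitFractions` (so per-split label counts match the
#' requested proportions up to rounding), and writes a manifest CSV.
#' Per-slide randomness is derived from the master seed in `params`, so the
#' same parameters regenerate an identical cohort.
#'
#' @param nPos,nNeg number of positive / negative slides (each >= 1).
#' @param params a [SynthParams-class] with the positive slides'
#'   `lesionFraction` (> 0); negatives are generated with lesion fraction 0.
#' @param splitFractions named numeric triple summing to 1, in the order
#'   train, validation, test.
#' @param dir output directory.
#' @param magnification nominal magnification tag for all slides.
#' @return the manifest data.frame (also written to `dir/manifest.csv`),
#'   with the ground-truth `tissue_mask_path` as an extra column.
#' @export
generateCohort <- function(nPos, nNeg, params,
                           splitFractions = c(train = 0.6, validation = 0.2,
                                              test = 0.2),
                           dir = tempdir(), magnification = "20x") {
  if (nPos < 1L || nNeg < 1L)
    stop("nPos and nNeg must each be >= 1 (the training queue alternates labels)")
  stopifnot(length(splitFractions) == 3L)
  if (is.null(names(splitFractions)))
    names(splitFractions) <- c("train", "validation", "test")
  if (params@lesionFraction <= 0)
    stop("params@lesionFraction must be > 0 for the positive slides")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  splits <- names(splitFractions)
  records <- list()
  idx <- 0L
  for (lab in c("adenocarcinoma", "benign")) {
    nLab <- if (lab == "adenocarcinoma") nPos else nNeg
    counts <- roundSplit(nLab, splitFractions)
    splitVec <- rep(splits, counts)
    for (i in seq_len(nLab)) {
      idx <- idx + 1L
      sid <- sprintf("slide_%04d", idx)
      p <- params
      p@lesionFraction <- if (lab == "adenocarcinoma") params@lesionFraction else 0
      p@seed <- deriveSeed(params@seed, sid)
      records[[idx]] <- generateSlide(p, label = lab, dir = dir,
                                      slideId = sid,
                                      magnification = magnification,
                                      split = splitVec[i])
    }
  }
  manifest <- do.call(rbind, records)
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
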