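# A small convolutional backbone implemented on base matrix algebra.
#
# The training pipeline is backbone-agnostic: it only needs named parameter
# tensors tagged by layer kind (convolution kernels, batch-normalization
# affine parameters, classifier head), a forward pass producing one
# positive-class probability per tile, and gradients for whichever subset of
# parameters is trainable. The default "tiny_cnn" is three conv(3x3,
# stride 2) -> batch-norm -> ReLU blocks followed by global average pooling
# and a single-logit linear head; convolutions are evaluated as im2col
# gather + one matrix product so the heavy lifting happens in BLAS.
#
# Batch tensors are stored as a dense matrix of (sample-major, y-major)
# spatial rows by channel columns: row (s-1)*H*W + y*W + x + 1 holds pixel
# (x, y) of sample s.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Create a convolutional backbone
#'
#' @param backbone `"tiny_cnn"`. The `"efficientnet_b1"` interface slot
#'   exists in [trainConfig()] but requires user-supplied pretrained
#'   weights, which this package does not ship.
#' @param inputChannels image channels (1 for grayscale slides).
#' @param channels integer vector of per-block output channels.
#' @param seed integer seed for He-normal weight initialization.
#' @return a `wsiModel` list with `params` (named tensors), `buffers`
#'   (batch-norm running statistics) and architecture metadata.
#' @export
createBackbone <- function(backbone = "tiny_cnn", inputChannels = 1L,
                           channels = c(8L, 16L, 32L), seed = 1L) {
  if (backbone != "tiny_cnn")
    stop("backbone '", backbone, "' requires user-supplied pretrained ",
         "weights; only 'tiny_cnn' can be constructed from scratch")
  k <- 3L
  params <- list(); buffers <- list()
  cin <- inputChannels
  withSeed(deriveSeed(seed, "init"), {
    for (b in seq_along(channels)) {
      cout <- channels[b]
      params[[paste0("conv", b, "_W")]] <-
        matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               nrow = k * k * cin, ncol = cout)
      params[[paste0("bn", b, "_gamma")]] <- rep(1, cout)
      params[[paste0("bn", b, "_beta")]] <- rep(0, cout)
      buffers[[paste0("bn", b, "_mean")]] <- rep(0, cout)
      buffers[[paste0("bn", b, "_var")]] <- rep(1, cout)
      cin <- cout
    }
    params$head_W <- matrix(stats::rnorm(cin, sd = sqrt(1 / cin)), ncol = 1)
    params$head_b <- 0
  })
  structure(list(backbone = backbone, inputChannels = inputChannels,
                 channels = channels, kernel = k, stride = 2L,
                 params = params, buffers = buffers),
            class = "wsiModel")
}

#' @export
print.wsiModel <- function(x, ...) {
  nPar <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("wsiModel '%s': blocks %s, %d parameters\n", x$backbone,
              paste(x$channels, collapse = "-"), nPar))
  invisible(x)
}

#' Names of trainable parameters under a fine-tuning mode
#'
#' In partial mode only the batch-normalization affine parameters
#' (scale/shift) and the final classifier's weights and bias are trainable;
#' every other tensor stays frozen. In full mode all parameters train.
#'
#' @param model a `wsiModel`.
#' @param mode `"partial"` or `"full"`.
#' @return character vector of parameter names.
#' @export
trainableParameterMask <- function(model, mode = c("partial", "full")) {
  mode <- match.arg(mode)
  nm <- names(model$params)
  if (mode == "full") return(nm)
  bn <- grep("^bn[0-9]+_(gamma|beta)$", nm, value = TRUE)
  if (!length(bn))
    stop("partial fine-tuning requires normalization layers, none found")
  c(bn, grep("^head_", nm, value = TRUE))
}

# im2col gather indices are pure functions of the geometry; cache them, and
# cache the batch-stacked variant, since every forward/backward pass reuses
# the same shapes.
.indexCache <- new.env(parent = emptyenv())

# Indices for one sample: P2 x k^2 matrix of input row indices.
convIndex <- function(H, W, k, stride) {
  key <- paste("ci", H, W, k, stride, sep = "/")
  ci <- .indexCache[[key]]
  if (!is.null(ci)) return(ci)
  H2 <- (H - k) %/% stride + 1L
  W2 <- (W - k) %/% stride + 1L
  pos <- expand.grid(ox = 0:(W2 - 1L), oy = 0:(H2 - 1L))  # x fastest: row-major
  idx <- matrix(0L, nrow = H2 * W2, ncol = k * k)
  for (ky in 0:(k - 1L)) for (kx in 0:(k - 1L)) {
    idx[, ky * k + kx + 1L] <-
      (pos$oy * stride + ky) * W + pos$ox * stride + kx + 1L
  }
  ci <- list(idx = idx, H2 = H2, W2 = W2)
  .indexCache[[key]] <- ci
  ci
}

# Batch-stacked gather indices: (Nb*P2) x k^2.
stackedIndex <- function(H, W, Nb, ci) {
  key <- paste("si", H, W, ci$H2, ci$W2, ncol(ci$idx), Nb, sep = "/")
  si <- .indexCache[[key]]
  if (!is.null(si)) return(si)
  P1 <- H * W; P2 <- nrow(ci$idx)
  offs <- rep((0:(Nb - 1L)) * P1, each = P2)
  si <- ci$idx[rep(seq_len(P2), times = Nb), , drop = FALSE] + offs
  .indexCache[[key]] <- si
  si
}

# Gather a batch tensor into im2col layout: (Nb*P2) x (k^2 * C).
im2col <- function(data, H, W, C, Nb, ci) {
  k2 <- ncol(ci$idx)
  si <- stackedIndex(H, W, Nb, ci)
  cols <- matrix(0, nrow(si), k2 * C)
  for (j in seq_len(k2)) {
    cols[, ((j - 1L) * C + 1L):(j * C)] <- data[si[, j], , drop = FALSE]
  }
  cols
}

# Scatter im2col gradients back onto the input tensor (inverse of im2col);
# for a fixed kernel offset the target rows are distinct, so plain indexed
# addition accumulates correctly across offsets.
col2im <- function(dcols, H, W, C, Nb, ci) {
  P1 <- H * W; k2 <- ncol(ci$idx)
  si <- stackedIndex(H, W, Nb, ci)
  dData <- matrix(0, Nb * P1, C)
  for (j in seq_len(k2)) {
    rows <- si[, j]
    dData[rows, ] <- dData[rows, ] + dcols[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dData
}

# Forward pass. `train` switches batch norm between batch statistics (with
# running-stat updates) and stored running statistics; inference therefore
# does not depend on batch composition.
cnnForward <- function(model, data, H, W, Nb, train = FALSE) {
  C <- model$inputChannels
  cache <- list(H = H, W = W, Nb = Nb, blocks = list())
  x <- data
  for (b in seq_along(model$channels)) {
    ci <- convIndex(H, W, model$kernel, model$stride)
    cols <- im2col(x, H, W, C, Nb, ci)
    Wb <- model$params[[paste0("conv", b, "_W")]]
    z <- cols %*% Wb
    gamma <- model$params[[paste0("bn", b, "_gamma")]]
    beta <- model$params[[paste0("bn", b, "_beta")]]
    if (train) {
      mu <- .colMeans(z, nrow(z), ncol(z))
      vr <- .colMeans(z * z, nrow(z), ncol(z)) - mu^2
      model$buffers[[paste0("bn", b, "_mean")]] <-
        BN_MOMENTUM * model$buffers[[paste0("bn", b, "_mean")]] + (1 - BN_MOMENTUM) * mu
      model$buffers[[paste0("bn", b, "_var")]] <-
        BN_MOMENTUM * model$buffers[[paste0("bn", b, "_var")]] + (1 - BN_MOMENTUM) * vr
    } else {
      mu <- model$buffers[[paste0("bn", b, "_mean")]]
      vr <- model$buffers[[paste0("bn", b, "_var")]]
    }
    istd <- 1 / sqrt(vr + BN_EPS)
    xhat <- sweep(sweep(z, 2, mu, "-"), 2, istd, "*")
    a <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    relu <- a > 0
    a[!relu] <- 0
    cache$blocks[[b]] <- list(ci = ci, cols = cols, xhat = xhat, istd = istd,
                              relu = relu, H = H, W = W, C = C)
    x <- a
    H <- ci$H2; W <- ci$W2; C <- model$channels[b]
  }
  P <- H * W
  sampleIdx <- rep(seq_len(Nb), each = P)
  pooled <- rowsum(x, sampleIdx, reorder = FALSE) / P
  logits <- pooled %*% model$params$head_W + model$params$head_b
  probs <- 1 / (1 + exp(-logits))
  cache$pooled <- pooled
  cache$P <- P
  list(probs = as.vector(probs), logits = as.vector(logits), cache = cache,
       model = model)
}

# Backward pass from d(loss)/d(logit); returns gradients for all parameters
# (the optimizer applies only the trainable subset).
cnnBackward <- function(model, cache, dlogit) {
  Nb <- cache$Nb
  grads <- list()
  dlog <- matrix(dlogit, ncol = 1)
  grads$head_W <- t(cache$pooled) %*% dlog
  grads$head_b <- sum(dlog)
  dpooled <- dlog %*% t(model$params$head_W)
  P <- cache$P
  dx <- dpooled[rep(seq_len(Nb), each = P), , drop = FALSE] / P
  for (b in rev(seq_along(model$channels))) {
    blk <- cache$blocks[[b]]
    gamma <- model$params[[paste0("bn", b, "_gamma")]]
    dx[!blk$relu] <- 0
    # batch-norm backward (batch statistics)
    n <- nrow(dx)
    grads[[paste0("bn", b, "_gamma")]] <- colSums(dx * blk$xhat)
    grads[[paste0("bn", b, "_beta")]] <- colSums(dx)
    dxhat <- sweep(dx, 2, gamma, "*")
    m1 <- .colMeans(dxhat, n, ncol(dxhat))
    m2 <- .colMeans(dxhat * blk$xhat, n, ncol(dxhat))
    dz <- sweep(sweep(dxhat, 2, m1, "-") - sweep(blk$xhat, 2, m2, "*"),
                2, blk$istd, "*")
    grads[[paste0("conv", b, "_W")]] <- t(blk$cols) %*% dz
    if (b > 1L) {
      dcols <- dz %*% t(model$params[[paste0("conv", b, "_W")]])
      dx <- col2im(dcols, blk$H, blk$W, blk$C, Nb, blk$ci)
    }
  }
  grads
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(model, grads, state, lr, beta1, beta2, trainable,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    model$params[[nm]] <- model$params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(model = model, state = state)
}

# Extract a batch tensor for tile rows that may span several slides;
# `images` is a named list of gray matrices keyed by slide id. Pixels are
# scaled to [-1, 1].
extractTileBatch <- function(images, tiles, tileSize) {
  if (is.matrix(images)) images <- list(images)
  Nb <- nrow(tiles)
  data <- matrix(0, Nb * tileSize * tileSize, 1)
  for (i in seq_len(Nb)) {
    gray <- if (length(images) == 1L && is.null(names(images))) images[[1L]]
            else images[[tiles$slide_id[i]]]
    if (is.null(gray)) stop("no image for slide ", tiles$slide_id[i])
    if (length(dim(gray)) == 3L) gray <- toGrayscale(gray)
    x0 <- tiles$x[i]; y0 <- tiles$y[i]
    if (x0 < 0 || y0 < 0 || x0 + tileSize > ncol(gray) ||
        y0 + tileSize > nrow(gray))
      stop("tile (", x0, ",", y0, ") out of image bounds")
    tile <- gray[(y0 + 1L):(y0 + tileSize), (x0 + 1L):(x0 + tileSize)]
    data[((i - 1L) * tileSize^2 + 1L):(i * tileSize^2), 1] <-
      as.vector(t(tile))  # y-major flattening (x fastest)
  }
  (data - 127.5) / 127.5
}

# One optimization step on a batch of tiles; binary cross-entropy loss.
trainStep <- function(model, optState, images, tiles, labels, tileSize, lr,
                      cfg, trainable) {
  data <- extractTileBatch(images, tiles, tileSize)
  Nb <- nrow(tiles)
  fw <- cnnForward(model, data, tileSize, tileSize, Nb, train = TRUE)
  model <- fw$model  # running-stat updates
  p <- clip(fw$probs, 1e-7, 1 - 1e-7)
  y <- as.numeric(labels)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dlogit <- (fw$probs - y) / Nb
  grads <- cnnBackward(model, fw$cache, dlogit)
  up <- adamStep(model, grads, optState, lr, cfg@beta1, cfg@beta2, trainable)
  list(model = up$model, optState = up$state, loss = loss)
}

# Eval-mode probabilities for a prepared batch tensor.
modelProbs <- function(model, data, tileSize, Nb) {
  cnnForward(model, data, tileSize, tileSize, Nb, train = FALSE)$probs
}
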