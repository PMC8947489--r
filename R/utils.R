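#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams, so that independent stages (slide geometry, textures,
#' queue shuffles, tile draws, weight init, bootstrap resampling) can be
#' reproduced in isolation. The derivation is a small string hash folded
#' into the master seed; it is stable across platforms and R sessions.
#'
#' @param master integer master seed.
#' @param name character scalar naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  # FNV-1a-style hash over the substream name, folded with the master seed
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(name)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((abs(master) + h) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Map slide labels to binary 0/1. Positive class is adenocarcinoma.
#' Convert slide labels to binary indicators
#'
#' @param labels character or numeric vector; `"adenocarcinoma"`,
#'   `"positive"` and `1` map to 1, `"benign"`, `"negative"` and `0` to 0.
#' @return integer vector of 0/1.
#' @export
asBinaryLabel <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  lab <- tolower(as.character(labels))
  out <- ifelse(lab %in% c("adenocarcinoma", "positive", "pos", "1"), 1L,
         ifelse(lab %in% c("benign", "negative", "neg", "0"), 0L, NA_integer_))
  if (anyNA(out)) stop("unrecognized label(s): ",
                       paste(unique(labels[is.na(out)]), collapse = ", "))
  out
}

# Short stable hash of an R object (used for run-manifest config hashes).
configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h1 <- 2166136261 %% 2147483647; h2 <- 40389
  for (b in utf8ToInt(s)) {
    h1 <- bitwXor(h1, b); h1 <- (h1 * 16777619) %% 2147483647
    h2 <- (h2 * 31 + b) %% 2147483647
  }
  sprintf("%08x%08x", h1, h2)
}
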