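# Shared fixtures, built in code and cached for the test run.

.fixtures <- new.env(parent = emptyenv())

# A small cohort of 256 px slides (64 px tiles downstream): 4 positive +
# 4 negative, needle cores, lesion fraction 0.3.
smallCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    dir <- file.path(tempdir(), "wsimine-fixture-cohort")
    params <- synthParams(imageSize = 256L, nCores = 2L,
                          coreShape = "needle", lesionFraction = 0.3,
                          seed = 101L)
    .fixtures$cohort <- generateCohort(
      4, 4, params, c(train = 0.5, validation = 0.25, test = 0.25),
      dir = dir)
  }
  .fixtures$cohort
}

# One positive slide record from the small cohort, with its image loaded.
smallSlide <- function() {
  man <- smallCohort()
  rec <- man[man$label == "adenocarcinoma", ][1, ]
  list(record = rec, image = readSlideImage(rec$image_path),
       tissue = wsimine:::readMaskImage(rec$tissue_mask_path),
       lesion = wsimine:::readMaskImage(rec$lesion_mask_path))
}

# A backbone whose head is zeroed: outputs exactly 0.5 for every tile.
constantHalfModel <- function() {
  m <- createBackbone(seed = 1L)
  m$params$head_W[] <- 0
  m$params$head_b <- 0
  m
}

# Independent exhaustive-search oracle for the Otsu threshold: scans all
# 255 splits of the 256-bin histogram maximizing w0*w1*(mu0-mu1)^2, lowest
# threshold on ties.
oracleOtsu <- function(counts) {
  best <- -Inf; bt <- NA_integer_
  lv <- 0:255
  for (t in 1:255) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lv[1:t] * counts[1:t]) / w0
    mu1 <- sum(lv[(t + 1):256] * counts[(t + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

# Pairwise (Mann-Whitney-style) AUC oracle: P(score_pos > score_neg) with
# ties counted half, by brute force over all positive-negative pairs.
oracleAuc <- function(cohort) {
  y <- asBinaryLabel(cohort$label)
  sp <- cohort$score[y == 1L]; sn <- cohort$score[y == 0L]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Full-sort oracle for hard-tile selection with row-major tie-break.
oracleHardTiles <- function(tiles, label, k) {
  ord <- if (asBinaryLabel(label) == 0L)
    order(-tiles$prob, tiles$y, tiles$x) else order(tiles$prob, tiles$y, tiles$x)
  out <- tiles[ord[seq_len(min(k, nrow(tiles)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random scored cohort with both labels present.
randomCohort <- function(n, ties = FALSE) {
  y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  s <- if (ties) sample(seq(0, 1, by = 0.1), n, replace = TRUE)
       else round(runif(n), 3)
  data.frame(slide_id = sprintf("s%03d", seq_len(n)),
             label = ifelse(y == 1L, "adenocarcinoma", "benign"),
             score = s, stringsAsFactors = FALSE)
}
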