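queueManifest <- function(nPos, nNeg) {
  data.frame(
    slide_id = c(sprintf("p%d", seq_len(nPos)), sprintf("n%d", seq_len(nNeg))),
    label = c(rep("adenocarcinoma", nPos), rep("benign", nNeg)),
    stringsAsFactors = FALSE)
}

test_that("queue emission strictly alternates labels", {
  q <- buildQueue(queueManifest(2, 2), seed = 3L)
  labs <- integer(4)
  for (i in 1:4) { nx <- queueNext(q); q <- nx$queue; labs[i] <- nx$label }
  expect_true(identical(labs, c(1L, 0L, 1L, 0L)) ||
              identical(labs, c(0L, 1L, 0L, 1L)))
  expect_error(buildQueue(queueManifest(3, 0)), "each label")
})

test_that("an exhausted label is oversampled so alternation continues", {
  q <- buildQueue(queueManifest(3, 1), seed = 7L)
  ep <- epochSlides(q)
  s <- ep$slides
  expect_equal(nrow(s), 6L)  # 2 * max(3, 1)
  expect_true(all(abs(diff(s$label)) == 1L))         # alternation
  expect_setequal(s$slide_id[s$label == 1L], c("p1", "p2", "p3"))
  expect_equal(sum(s$label == 0L & s$oversampled), 2L)  # n1 re-drawn twice
  expect_true(all(s$slide_id[s$label == 0L] == "n1"))
})

test_that("queue order is deterministic given the seed and reshuffles by epoch", {
  m <- queueManifest(4, 4)
  e1 <- epochSlides(buildQueue(m, seed = 5L))
  e2 <- epochSlides(buildQueue(m, seed = 5L))
  expect_identical(e1$slides, e2$slides)
  eNext <- epochSlides(e1$queue)
  expect_false(identical(e1$slides$slide_id, eNext$slides$slide_id))
})

test_that("balanced batches hold batchSize/numLabels tiles per label", {
  man <- queueManifest(3, 3)
  pools <- lapply(seq_len(6), function(i) {
    data.frame(slide_id = man$slide_id[i], x = seq(0, 96, by = 32),
               y = 0L, tile_size = 32L, tissue_fraction = 1)
  })
  names(pools) <- man$slide_id
  q <- buildQueue(man, seed = 2L)
  sb <- sampleBalancedBatch(q, pools, miningConfig(), seed = 4L)
  expect_equal(nrow(sb$batch), 32L)
  expect_equal(sum(sb$batch$label == 1L), 16L)
  expect_equal(sum(sb$batch$label == 0L), 16L)
  expect_equal(length(unique(sb$batch$slide_id)), 2L)
})

test_that("a slide with a single tile is oversampled with replacement", {
  man <- queueManifest(1, 1)
  pools <- list(
    p1 = data.frame(slide_id = "p1", x = 0L, y = 0L, tile_size = 32L,
                    tissue_fraction = 1),
    n1 = data.frame(slide_id = "n1", x = seq(0, 619, by = 20), y = 0L,
                    tile_size = 32L, tissue_fraction = 1))
  q <- buildQueue(man, seed = 1L)
  sb <- sampleBalancedBatch(q, pools, miningConfig(), seed = 1L)
  pos <- sb$batch[sb$batch$label == 1L, ]
  expect_equal(nrow(pos), 16L)
  expect_true(all(pos$x == 0L))  # the only tile, repeated
  neg <- sb$batch[sb$batch$label == 0L, ]
  expect_equal(length(unique(neg$x)), 16L)  # enough tiles: no replacement
})

test_that("empty tile pools are skipped with a warning, or error when a label has none", {
  man <- queueManifest(2, 1)
  pools <- list(
    p1 = data.frame(slide_id = "p1", x = 0L, y = 0L, tile_size = 32L,
                    tissue_fraction = 1)[0, ],
    p2 = data.frame(slide_id = "p2", x = 0L, y = 0L, tile_size = 32L,
                    tissue_fraction = 1),
    n1 = data.frame(slide_id = "n1", x = 0L, y = 0L, tile_size = 32L,
                    tissue_fraction = 1))
  q <- buildQueue(man, seed = 6L)
  expect_warning(sb <- sampleBalancedBatch(q, pools, miningConfig(), seed = 2L),
                 "empty tile pool")
  expect_true(all(sb$batch$slide_id[sb$batch$label == 1L] == "p2"))

  pools$p2 <- pools$p1
  q2 <- buildQueue(man, seed = 6L)
  expect_error(suppressWarnings(
    sampleBalancedBatch(q2, pools, miningConfig(), seed = 2L)), "empty")
})

test_that("over one epoch every training slide contributes at least one tile", {
  man <- queueManifest(5, 3)
  pools <- lapply(man$slide_id, function(id)
    data.frame(slide_id = id, x = seq(0, 255, by = 16), y = 0L,
               tile_size = 16L, tissue_fraction = 1))
  names(pools) <- man$slide_id
  q <- buildQueue(man, seed = 8L)
  seen <- character(0)
  for (i in seq_len(max(5, 3))) {
    sb <- sampleBalancedBatch(q, pools, miningConfig(), seed = 10L + i)
    q <- sb$queue
    seen <- union(seen, unique(sb$batch$slide_id))
  }
  expect_setequal(seen, man$slide_id)
})

test_that("hard-tile selection matches the full-sort oracle on the worked cases", {
  tiles <- data.frame(slide_id = "s", x = c(0L, 32L, 64L), y = 0L,
                      tile_size = 32L, tissue_fraction = 1,
                      prob = c(0.9, 0.2, 0.5))
  pm <- new("TileProbabilityMap", slideId = "s", tileSize = 32L,
            stride = 32L, tiles = tiles)
  neg <- selectHardTiles(pm, "benign", 2L)
  expect_equal(neg$prob, c(0.9, 0.5))    # highest-probability tiles
  pos <- selectHardTiles(pm, "adenocarcinoma", 2L)
  expect_equal(pos$prob, c(0.2, 0.5))    # lowest-probability tiles
  expect_equal(nrow(selectHardTiles(pm, "benign", 10L)), 3L)
  empty <- new("TileProbabilityMap", slideId = "s", tileSize = 32L,
               stride = 32L, tiles = tiles[0, ])
  expect_error(selectHardTiles(empty, "benign", 2L), "empty")
})

test_that("hard-tile selection matches the oracle on random instances with ties", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    tiles <- data.frame(
      slide_id = "s",
      x = sample(seq(0L, 3200L, by = 32L), n, replace = TRUE),
      y = sample(seq(0L, 3200L, by = 32L), n, replace = TRUE),
      tile_size = 32L, tissue_fraction = 1,
      prob = sample(seq(0, 1, by = 0.05), n, replace = TRUE))  # many ties
    pm <- new("TileProbabilityMap", slideId = "s", tileSize = 32L,
              stride = 32L, tiles = tiles)
    k <- sample(1:16, 1)
    lab <- sample(c("benign", "adenocarcinoma"), 1)
    expect_identical(selectHardTiles(pm, lab, k),
                     oracleHardTiles(tiles, lab, k))
  }
})

test_that("the mining switch fires exactly when the minimum is patience-stale", {
  expect_false(shouldSwitchToMining(c(0.9, 0.8, 0.7), 2L))
  expect_true(shouldSwitchToMining(c(0.9, 0.8, 0.81, 0.82), 2L))
  expect_false(shouldSwitchToMining(c(0.9), 2L))
  # a plateau at the minimum is not an improvement
  expect_true(shouldSwitchToMining(c(0.9, 0.8, 0.8, 0.8), 2L))
  expect_false(shouldSwitchToMining(c(0.9, 0.8, 0.8), 2L) &&
               !shouldSwitchToMining(c(0.9, 0.8, 0.8), 2L))
})

test_that("the mining pool releases exactly N tiles FIFO", {
  mk <- function(ids) data.frame(slide_id = "s", x = ids, y = 0L,
                                 tile_size = 32L, tissue_fraction = 1)
  upd <- miningPoolUpdate(NULL, mk(1:8), 256L)
  expect_false(upd$ready)
  upd <- miningPoolUpdate(mk(1:250), mk(251:258), 256L)
  expect_true(upd$ready)
  expect_equal(nrow(upd$released), 256L)
  expect_equal(upd$released$x, 1:256)      # arrival order
  expect_equal(upd$pool$x, 257:258)        # retained tail

  # released batches partition the stream in arrival order
  pool <- NULL; released <- integer(0); fed <- integer(0)
  for (b in 1:40) {
    sel <- mk(((b - 1) * 8 + 1):(b * 8)); fed <- c(fed, sel$x)
    upd <- miningPoolUpdate(pool, sel, 64L)
    pool <- upd$pool
    if (upd$ready) released <- c(released, upd$released$x)
  }
  expect_equal(released, fed[seq_along(released)])
})
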