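test_that("the learning-rate schedule decays by 0.95 every 2 epochs", {
  cfg <- trainConfig()
  expect_equal(lrAtEpoch(0, cfg), 0.001)
  expect_equal(lrAtEpoch(1, cfg), 0.001)
  expect_equal(lrAtEpoch(2, cfg), 0.00095)
  expect_equal(lrAtEpoch(4, cfg), 0.0009025)
  expect_equal(lrAtEpoch(0:5, cfg),
               0.001 * 0.95^floor((0:5) / 2))
})

test_that("partial fine-tuning marks exactly the norm affine and head tensors", {
  m <- createBackbone(seed = 1L, channels = c(4L, 6L))  # 2 norm layers
  partial <- trainableParameterMask(m, "partial")
  expect_setequal(partial, c("bn1_gamma", "bn1_beta", "bn2_gamma",
                             "bn2_beta", "head_W", "head_b"))
  expect_length(partial, 6L)
  full <- trainableParameterMask(m, "full")
  expect_setequal(full, names(m$params))
  noNorm <- m
  noNorm$params <- m$params[c("conv1_W", "head_W", "head_b")]
  expect_error(trainableParameterMask(noNorm, "partial"), "normalization")
})

test_that("backbones without shippable pretrained weights cannot be constructed", {
  expect_error(createBackbone("efficientnet_b1"), "pretrained")
})

test_that("frozen parameters are bit-identical after partial-mode training steps", {
  set.seed(42)
  model <- createBackbone(seed = 7L)
  init <- model$params
  trainable <- trainableParameterMask(model, "partial")
  frozen <- setdiff(names(model$params), trainable)
  opt <- wsimine:::adamInit(model$params)
  cfg <- trainConfig()
  img <- matrix(sample(0:255, 128 * 128, replace = TRUE), 128)
  tiles <- data.frame(slide_id = "s",
                      x = rep(seq(0L, 96L, by = 32L), 2),
                      y = rep(c(0L, 64L), each = 4), tile_size = 32L,
                      tissue_fraction = 1)
  y <- rep(c(0, 1), 4)
  for (step in 1:3) {
    st <- wsimine:::trainStep(model, opt, list(s = img), tiles, y, 32L,
                              0.001, cfg, trainable)
    model <- st$model; opt <- st$optState
  }
  for (nm in frozen) expect_identical(model$params[[nm]], init[[nm]])
  for (nm in trainable) expect_false(identical(model$params[[nm]], init[[nm]]))
})

test_that("training stops when validation stalls and returns the best checkpoint", {
  man <- smallCohort()
  # stubbed evaluator: 1.0, 0.9, 0.8, 0.7, then flat at 0.7 from epoch 3 on
  stub <- function(model, epoch) max(0.7, 1.0 - 0.1 * epoch)
  seen <- new.env(parent = emptyenv())
  hook <- function(model, epoch, valLoss) {
    assign(sprintf("e%d", epoch), model, envir = seen)
  }
  cfg <- trainConfig(earlyStopPatience = 10L, maxEpochs = 50L,
                     valTilesPerSlide = 4L, seed = 5L)
  outDir <- withr::local_tempdir()
  f <- fit(man, cfg, miningConfig(N = 32L), tileSize = 64L,
           evaluator = stub, epochHook = hook, outDir = outDir)
  expect_equal(max(f$history$epoch), 13L)   # plateau from 3 + patience 10
  expect_equal(f$bestEpoch, 3L)
  expect_identical(f$model, get("e3", envir = seen))
  expect_equal(f$bestValLoss, 0.7)
  expect_equal(f$bestValLoss, min(f$history$val_loss))
  # phase switched to mining exactly once, two epochs after the minimum
  phases <- f$history$phase
  expect_equal(phases[1:6], c(rep("random_sampling", 6)))
  expect_true(all(phases[7:14] == "hard_mining"))
  # artifacts: per-epoch log, final checkpoint, resumable mining state
  expect_true(file.exists(file.path(outDir, "training_log.jsonl")))
  expect_true(file.exists(file.path(outDir, "checkpoint.rds")))
  ms <- jsonlite::read_json(file.path(outDir, "mining_state.json"))
  expect_equal(ms$phase, "hard_mining")
  expect_gte(ms$pool_size, 0L)
})

test_that("fit requires a validation split and both training labels", {
  man <- smallCohort()
  noVal <- man[man$split != "validation", ]
  expect_error(fit(noVal, trainConfig(), miningConfig(), tileSize = 64L),
               "validation")
  oneLabel <- man
  oneLabel$label[oneLabel$split == "train"] <- "benign"
  expect_error(fit(oneLabel, trainConfig(), miningConfig(), tileSize = 64L),
               "both labels")
})

test_that("validation loss is ln 2 for a coin-flip model and permutation-invariant", {
  man <- smallCohort()
  valM <- man[man$split == "validation", ]
  m <- constantHalfModel()
  l <- validationLoss(m, valM, tileSize = 64L, valTilesPerSlide = 8L,
                      seed = 3L)
  expect_equal(l, log(2), tolerance = 1e-12)
  # clipping contract: perfect predictions give a loss below 1e-6
  expect_lt(wsimine:::bceLoss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  # mean over tiles: invariant to order
  p <- runif(20); y <- rep(c(0, 1), 10)
  o <- sample(20)
  expect_equal(wsimine:::bceLoss(p, y), wsimine:::bceLoss(p[o], y[o]))
})

test_that("two runs with identical seeds produce identical histories", {
  man <- smallCohort()
  cfg <- trainConfig(maxEpochs = 3L, earlyStopPatience = 10L,
                     valTilesPerSlide = 8L, seed = 17L)
  f1 <- fit(man, cfg, miningConfig(N = 32L), tileSize = 64L)
  f2 <- fit(man, cfg, miningConfig(N = 32L), tileSize = 64L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})
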