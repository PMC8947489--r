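test_that("benign slides carry no lesion pixels and reject inconsistent requests", {
  d <- withr::local_tempdir()
  p <- synthParams(imageSize = 128L, nCores = 1L, lesionFraction = 0,
                   seed = 5L)
  rec <- generateSlide(p, "benign", dir = d, slideId = "b1")
  lesion <- wsimine:::readMaskImage(rec$lesion_mask_path)
  expect_false(any(lesion))
  expect_equal(rec$label, "benign")

  pPos <- synthParams(imageSize = 128L, lesionFraction = 0.2, seed = 5L)
  expect_error(generateSlide(pPos, "benign", dir = d, slideId = "b2"),
               "inconsistent")
  expect_error(generateSlide(p, "adenocarcinoma", dir = d, slideId = "b3"),
               "inconsistent")
})

test_that("identical parameters and seed produce byte-identical images", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p <- synthParams(imageSize = 128L, lesionFraction = 0.25, seed = 77L)
  r1 <- generateSlide(p, "adenocarcinoma", dir = d1, slideId = "s")
  r2 <- generateSlide(p, "adenocarcinoma", dir = d2, slideId = "s")
  expect_identical(readBin(r1$image_path, "raw", 1e7),
                   readBin(r2$image_path, "raw", 1e7))
})

test_that("lesion occupies the requested fraction of tissue and stays inside it", {
  s <- smallSlide()  # lesionFraction 0.3
  A <- sum(s$tissue)
  frac <- sum(s$lesion) / A
  expect_gte(frac, 0.27)
  expect_lte(frac, 0.33)
  expect_true(all(s$tissue[s$lesion]))
})

test_that("tissue is darker than background minus the texture contrast", {
  for (shape in c("needle", "blob")) {
    d <- withr::local_tempdir()
    p <- synthParams(imageSize = 192L, nCores = 2L, coreShape = shape,
                     lesionFraction = 0.3, textureContrast = 60,
                     backgroundLevel = 245L, seed = 13L)
    rec <- generateSlide(p, "adenocarcinoma", dir = d, slideId = shape)
    img <- readSlideImage(rec$image_path)
    tissue <- wsimine:::readMaskImage(rec$tissue_mask_path)
    expect_lt(mean(img[tissue]), 245 - 60)
    expect_gt(mean(img[!tissue]), 240)
  }
})

test_that("cohort splits match requested proportions up to rounding and are balanced", {
  d <- withr::local_tempdir()
  p <- synthParams(imageSize = 96L, nCores = 1L, lesionFraction = 0.3,
                   seed = 9L)
  man <- generateCohort(5, 5, p, c(train = 0.6, validation = 0.2,
                                   test = 0.2), dir = d)
  counts <- table(man$split)
  expect_equal(unname(counts[c("train", "validation", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  byLab <- table(man$split, man$label)
  expect_true(all(byLab[, "adenocarcinoma"] == byLab[, "benign"]))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  reread <- readManifest(file.path(d, "manifest.csv"))
  expect_equal(nrow(reread), 10L)
})

test_that("degenerate cohorts error and tiny splits warn", {
  p <- synthParams(imageSize = 96L, nCores = 1L, lesionFraction = 0.3)
  expect_error(generateCohort(0, 5, p, dir = withr::local_tempdir()),
               "nPos")
  w <- testthat::capture_warnings(
    generateCohort(1, 1, p, c(train = 0.6, validation = 0.2, test = 0.2),
                   dir = withr::local_tempdir()))
  expect_true(all(grepl("received 0 slides", w)))
  expect_length(w, 2L)  # one rounding warning per label
})

test_that("a cohort regenerates identically from the same master seed", {
  p <- synthParams(imageSize = 96L, nCores = 1L, lesionFraction = 0.3,
                   seed = 31L)
  fr <- c(train = 0.5, validation = 0.5, test = 0)
  m1 <- generateCohort(2, 2, p, fr, dir = withr::local_tempdir())
  m2 <- generateCohort(2, 2, p, fr, dir = withr::local_tempdir())
  expect_identical(m1$slide_id, m2$slide_id)
  expect_identical(m1$label, m2$label)
  expect_identical(m1$split, m2$split)
  expect_identical(readBin(m1$image_path[1], "raw", 1e6),
                   readBin(m2$image_path[1], "raw", 1e6))
})

test_that("10x slides are generated at half the linear resolution", {
  d <- withr::local_tempdir()
  p <- synthParams(imageSize = 128L, nCores = 1L, lesionFraction = 0,
                   seed = 3L)
  r20 <- generateSlide(p, "benign", dir = d, slideId = "m20",
                       magnification = "20x")
  r10 <- generateSlide(p, "benign", dir = d, slideId = "m10",
                       magnification = "10x")
  expect_equal(dim(readSlideImage(r20$image_path)), c(128L, 128L))
  expect_equal(dim(readSlideImage(r10$image_path)), c(64L, 64L))
})
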