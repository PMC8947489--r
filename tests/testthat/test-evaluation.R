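cohortOf <- function(scoresPos, scoresNeg) {
  data.frame(
    slide_id = sprintf("s%d", seq_len(length(scoresPos) + length(scoresNeg))),
    label = c(rep("adenocarcinoma", length(scoresPos)),
              rep("benign", length(scoresNeg))),
    score = c(scoresPos, scoresNeg), stringsAsFactors = FALSE)
}

test_that("confusion counts follow the score >= t convention", {
  co <- cohortOf(0.9, 0.1)
  expect_equal(confusionAtThreshold(co, 0.5),
               list(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  allPos <- confusionAtThreshold(co, 0)
  expect_equal(allPos$TP + allPos$FP, 2L)   # t = 0 calls everything positive
  allNeg <- confusionAtThreshold(co, 0.91)
  expect_equal(allNeg$TN + allNeg$FN, 2L)
  # ties at the threshold are called positive
  expect_equal(confusionAtThreshold(cohortOf(0.5, 0.2), 0.5)$TP, 1L)
})

test_that("TPR and FPR implement their defining ratios with denominator guards", {
  expect_equal(tpr(list(TP = 3L, FN = 1L, FP = 0L, TN = 0L)), 0.75)
  expect_equal(fpr(list(FP = 0L, TN = 5L, TP = 0L, FN = 0L)), 0.0)
  expect_equal(tpr(list(TP = 0L, FN = 4L, FP = 0L, TN = 0L)), 0.0)
  expect_error(tpr(list(TP = 0L, FN = 0L, FP = 1L, TN = 1L)), "no positives")
  expect_error(fpr(list(TP = 1L, FN = 1L, FP = 0L, TN = 0L)), "no negatives")
})

test_that("ROC endpoints and degenerate cohorts behave", {
  perfect <- cohortOf(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(auc(perfect), 1.0)
  constant <- cohortOf(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(auc(constant), 0.5)
  curve <- rocCurve(perfect)  # descending threshold: (0,0) up to (1,1)
  expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
  expect_equal(c(curve$fpr[nrow(curve)], curve$tpr[nrow(curve)]), c(1, 1))
  # threshold 0 calls everything positive; above the max score, nothing
  expect_equal(curve$threshold[nrow(curve)], 0)
  single <- cohortOf(c(0.4, 0.6), numeric(0))
  expect_error(rocCurve(single), "both labels")
})

test_that("threshold-sweep AUC equals the pairwise oracle within 1e-9", {
  set.seed(19)
  for (i in 1:40) {
    co <- randomCohort(sample(4:120, 1), ties = i %% 2 == 0)
    expect_equal(auc(co), oracleAuc(co), tolerance = 1e-9)
  }
})

test_that("AUC is invariant under label swap with score flip", {
  set.seed(23)
  co <- randomCohort(60, ties = TRUE)
  flipped <- co
  flipped$label <- ifelse(co$label == "benign", "adenocarcinoma", "benign")
  flipped$score <- 1 - co$score
  expect_equal(auc(flipped), auc(co), tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  co <- randomCohort(80)
  ref <- suppressMessages(as.numeric(pROC::auc(
    asBinaryLabel(co$label), co$score, direction = "<")))
  expect_equal(auc(co), ref, tolerance = 1e-12)
})

test_that("log loss matches its closed forms", {
  expect_equal(logLoss(cohortOf(c(0.5, 0.5), c(0.5, 0.5))), log(2))
  expect_equal(logLoss(cohortOf(0.25, numeric(0))), -log(0.25))
  expect_lt(logLoss(cohortOf(1, 0)), 1e-9)     # clipped perfect predictions
})

test_that("summary metrics evaluate the four confusion formulas", {
  # TP=45, FN=5, TN=48, FP=2 at t = 0.5
  co <- cohortOf(c(rep(0.9, 45), rep(0.1, 5)), c(rep(0.1, 48), rep(0.9, 2)))
  m <- summaryMetrics(co, 0.5)
  expect_equal(m$accuracy, 0.93)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.96)
  expect_equal(m$f1, 2 * 45 / (2 * 45 + 2 + 5), tolerance = 1e-12)

  perfect <- cohortOf(rep(0.99, 5), rep(0.01, 5))
  expect_equal(unlist(summaryMetrics(perfect, 0.5)),
               c(accuracy = 1, sensitivity = 1, specificity = 1, f1 = 1))

  allPos <- cohortOf(rep(0.9, 5), rep(0.9, 5))
  m2 <- summaryMetrics(allPos, 0.5)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$sensitivity, 1.0)
  expect_equal(m2$specificity, 0.0)
})

test_that("bootstrap CIs are deterministic order statistics and collapse for constants", {
  set.seed(31)
  co <- randomCohort(40)
  constCI <- bootstrapCI(co, function(x) 0.42, nIter = 100L, seed = 9L)
  expect_equal(unname(constCI), c(0.42, 0.42))
  ci1 <- bootstrapCI(co, auc, nIter = 200L, seed = 9L)
  ci2 <- bootstrapCI(co, auc, nIter = 200L, seed = 9L)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lo"]], auc(co))
  expect_gte(ci1[["hi"]], auc(co))
})

test_that("the metric report carries all six metrics with ordered CIs", {
  set.seed(37)
  co <- randomCohort(30)
  rep6 <- metricReport(co, threshold = 0.5, nBootstrap = 50L, seed = 2L)
  m <- metricTable(rep6)
  expect_setequal(m$metric, c("auc", "log_loss", "accuracy", "sensitivity",
                              "specificity", "f1"))
  expect_true(all(m$lo <= m$hi))
  d <- withr::local_tempdir()
  writeMetricReport(rep6, co, d)
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_true(all(c("auc", "log_loss", "accuracy", "sensitivity",
                    "specificity", "f1") %in% names(js)))
  expect_true(file.exists(file.path(d, "roc_curve.tsv")))
})

test_that("percentile CIs cover a closed-form binormal AUC", {
  # scores from two normals squashed to [0,1]; the squashing is monotone so
  # the AUC equals the binormal closed form Phi(dmu / sqrt(s1^2 + s2^2))
  dmu <- 1.2; s <- 1
  trueAuc <- pnorm(dmu / sqrt(2 * s^2))
  hits <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    co <- data.frame(
      slide_id = sprintf("s%d", 1:80),
      label = rep(c("adenocarcinoma", "benign"), each = 40),
      score = plogis(c(rnorm(40, dmu, s), rnorm(40, 0, s))),
      stringsAsFactors = FALSE)
    ci <- bootstrapCI(co, auc, nIter = 300L, seed = r)
    if (ci[["lo"]] <= trueAuc && trueAuc <= ci[["hi"]]) hits <- hits + 1L
  }
  expect_gte(hits, 0.85 * reps)
})
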