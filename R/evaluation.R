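# Slide-level evaluation: confusion counts, TPR/FPR, ROC by threshold
# sweep, trapezoidal AUC, log loss, summary metrics, and percentile
# bootstrap confidence intervals over resampled slides.
#
# A scored cohort is a data.frame with columns slide_id, label, score
# (scores in [0, 1]); a positive call is score >= threshold, so ties at the
# threshold are called positive.

checkCohort <- function(cohort, bothLabels = TRUE) {
  stopifnot(all(c("label", "score") %in% names(cohort)))
  if (any(cohort$score < 0 | cohort$score > 1))
    stop("scores must be in [0, 1]")
  y <- asBinaryLabel(cohort$label)
  if (bothLabels && length(unique(y)) < 2L)
    stop("cohort must contain both labels")
  y
}

#' Confusion counts at a threshold
#'
#' @param cohort scored cohort (`slide_id, label, score`).
#' @param t threshold in \[0, 1\]; a slide is called positive when
#'   `score >= t`.
#' @return named list with `TP, FP, TN, FN`.
#' @export
confusionAtThreshold <- function(cohort, t) {
  stopifnot(t >= 0, t <= 1)
  y <- checkCohort(cohort, bothLabels = FALSE)
  call <- cohort$score >= t
  list(TP = sum(call & y == 1L), FP = sum(call & y == 0L),
       TN = sum(!call & y == 0L), FN = sum(!call & y == 1L))
}

#' True and false positive rates
#'
#' `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`.
#'
#' @param c confusion counts from [confusionAtThreshold()].
#' @return scalar rate.
#' @export
tpr <- function(c) {
  if (c$TP + c$FN == 0L) stop("no positives in cohort: TPR undefined")
  c$TP / (c$TP + c$FN)
}

#' @rdname tpr
#' @export
fpr <- function(c) {
  if (c$FP + c$TN == 0L) stop("no negatives in cohort: FPR undefined")
  c$FP / (c$FP + c$TN)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the threshold over every distinct score plus the sentinels 0 and
#' just above the maximum score, computing TPR and FPR at each; the curve
#' runs from (1, 1) at threshold 0 to (0, 0) above the top score.
#'
#' @param cohort scored cohort with both labels present.
#' @return data.frame `threshold, fpr, tpr`, sorted by descending threshold
#'   (ascending FPR).
#' @export
rocCurve <- function(cohort) {
  y <- checkCohort(cohort)
  s <- cohort$score
  P <- sum(y == 1L); N <- sum(y == 0L)
  o <- order(s, decreasing = TRUE)
  ss <- s[o]; sy <- y[o]
  # cumulative positive calls walking the thresholds down the sorted scores;
  # at threshold = a score value, every slide with that score is called
  # positive, so take the last index of each tied run
  last <- which(!duplicated(ss, fromLast = TRUE))
  cumTP <- cumsum(sy == 1L)[last]
  cumFP <- cumsum(sy == 0L)[last]
  thr <- ss[last]
  # sentinels: above the top score nothing is positive; at 0 everything is
  thr <- c(max(s) + 1e-9, thr)
  tp <- c(0, cumTP); fp <- c(0, cumFP)
  if (thr[length(thr)] > 0) {
    thr <- c(thr, 0); tp <- c(tp, P); fp <- c(fp, N)
  }
  data.frame(threshold = thr, fpr = fp / N, tpr = tp / P)
}

#' Area under the ROC curve
#'
#' Trapezoidal rule over the threshold-sweep curve; equivalent to the
#' probability that a random positive outscores a random negative, with
#' ties counted half.
#'
#' @param curve data.frame from [rocCurve()], or a scored cohort (in which
#'   case the curve is computed first).
#' @return scalar AUC.
#' @export
auc <- function(curve) {
  if (!all(c("fpr", "tpr") %in% names(curve))) curve <- rocCurve(curve)
  o <- order(curve$fpr, curve$tpr)
  x <- curve$fpr[o]; y <- curve$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Slide-level log loss
#'
#' Mean binary cross-entropy of the slide scores against the slide labels,
#' with scores clipped to `[eps, 1 - eps]`.
#'
#' @param cohort scored cohort.
#' @param eps clipping epsilon.
#' @return scalar loss.
#' @export
logLoss <- function(cohort, eps = 1e-15) {
  y <- checkCohort(cohort, bothLabels = FALSE)
  p <- clip(cohort$score, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Accuracy, sensitivity, specificity and F1 at a threshold
#'
#' @param cohort scored cohort with both labels present.
#' @param t operating threshold (default 0.5).
#' @return named list `accuracy, sensitivity, specificity, f1`.
#' @export
summaryMetrics <- function(cohort, t = 0.5) {
  checkCohort(cohort)
  cc <- confusionAtThreshold(cohort, t)
  list(accuracy = (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN),
       sensitivity = tpr(cc),
       specificity = cc$TN / (cc$TN + cc$FP),
       f1 = 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples slides with replacement `nIter` times, recomputes the
#' statistic on each resample, and returns the 2.5th and 97.5th percentiles
#' of the bootstrap distribution as order statistics. Resamples missing a
#' label are re-drawn so `nIter` stays fixed; if re-drawing fails
#' persistently the statistic is deemed undefined on the cohort.
#'
#' @param cohort scored cohort.
#' @param statistic `function(cohort) -> scalar`.
#' @param nIter bootstrap iterations (default 1000).
#' @param seed integer seed; the interval is deterministic given the seed.
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lo, hi)`.
#' @export
bootstrapCI <- function(cohort, statistic, nIter = 1000L, seed = 1L,
                        level = 0.95) {
  n <- nrow(cohort)
  stopifnot(n >= 2L)
  y <- checkCohort(cohort)
  stats <- withSeed(deriveSeed(seed, "bootstrap"), {
    out <- numeric(nIter)
    redraws <- 0L
    for (i in seq_len(nIter)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        redraws <- redraws + 1L
        if (redraws > 20L * nIter)
          stop("statistic undefined on most resamples (degenerate labels)")
      }
      out[i] <- statistic(cohort[idx, , drop = FALSE])
    }
    out
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats, c(a, 1 - a), type = 1, names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Full metric report with bootstrap confidence intervals
#'
#' Computes AUC, log loss, accuracy, sensitivity, specificity and F1 on the
#' scored cohort, each with a percentile-bootstrap 95% confidence interval
#' over resampled slides.
#'
#' @param cohort scored cohort.
#' @param threshold operating threshold for the confusion metrics.
#' @param nBootstrap bootstrap iterations.
#' @param seed integer seed.
#' @return a [MetricReport-class].
#' @export
metricReport <- function(cohort, threshold = 0.5, nBootstrap = 1000L,
                         seed = 1L) {
  checkCohort(cohort)
  statFns <- list(
    auc = function(co) auc(co),
    log_loss = function(co) logLoss(co),
    accuracy = function(co) summaryMetrics(co, threshold)$accuracy,
    sensitivity = function(co) summaryMetrics(co, threshold)$sensitivity,
    specificity = function(co) summaryMetrics(co, threshold)$specificity,
    f1 = function(co) summaryMetrics(co, threshold)$f1)
  rows <- lapply(names(statFns), function(nm) {
    ci <- bootstrapCI(cohort, statFns[[nm]], nBootstrap,
                      seed = deriveSeed(seed, nm))
    data.frame(metric = nm, estimate = statFns[[nm]](cohort),
               lo = ci[["lo"]], hi = ci[["hi"]], stringsAsFactors = FALSE)
  })
  new("MetricReport", metrics = do.call(rbind, rows),
      nBootstrap = as.integer(nBootstrap), threshold = threshold,
      seed = as.integer(seed))
}

#' Write a metric report and ROC curve to disk
#'
#' @param report a [MetricReport-class].
#' @param cohort the scored cohort the report was computed on.
#' @param dir output directory; writes `metrics.json`, `roc_curve.tsv` and
#'   (optionally) `roc_curve.png`.
#' @param plot also render a ROC plot PNG.
#' @return `dir`, invisibly.
#' @export
writeMetricReport <- function(report, cohort, dir, plot = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- metricTable(report)
  out <- lapply(seq_len(nrow(m)), function(i)
    list(estimate = m$estimate[i], ci_lo = m$lo[i], ci_hi = m$hi[i]))
  names(out) <- m$metric
  out$n_bootstrap <- report@nBootstrap
  out$threshold <- report@threshold
  jsonlite::write_json(out, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  curve <- rocCurve(cohort)
  utils::write.table(curve, file.path(dir, "roc_curve.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (plot) {
    grDevices::png(file.path(dir, "roc_curve.png"), width = 600, height = 600)
    on.exit(grDevices::dev.off())
    plot(curve$fpr, curve$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "False positive rate", ylab = "True positive rate",
         main = sprintf("ROC (AUC = %.4f)", auc(curve)))
    graphics::abline(0, 1, lty = 2, col = "gray")
  }
  invisible(dir)
}
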