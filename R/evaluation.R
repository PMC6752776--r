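# Evaluation surface for left-eye detection: confusion matrix, proportions
# with Wilson 95% intervals, ROC by threshold sweep, AUC (Mann-Whitney,
# ties counting one half) with a DeLong 95% interval.

#' Confusion counts with the left eye as positive class
#'
#' @param predictions,truths Equal-length character vectors of `"left"` /
#'   `"right"` labels.
#' @return Named integer vector `c(tp, fn, fp, tn)`.
#' @examples
#' confusionCounts(c("left", "left", "right", "right"),
#'                 c("left", "left", "right", "right"))
#' @export
confusionCounts <- function(predictions, truths) {
  .stopIf(length(predictions) == 0L ||
            length(predictions) != length(truths),
          "predictions and truths must be non-empty and of equal length")
  c(tp = sum(predictions == .LEFT & truths == .LEFT),
    fn = sum(predictions == .RIGHT & truths == .LEFT),
    fp = sum(predictions == .LEFT & truths == .RIGHT),
    tn = sum(predictions == .RIGHT & truths == .RIGHT))
}

.wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Accuracy, sensitivity and specificity with Wilson intervals
#'
#' Point estimates from the 2x2 table (left eye positive) with Wilson
#' score 95% confidence intervals.
#'
#' @param cm Named counts `c(tp, fn, fp, tn)` from [confusionCounts()].
#' @return A list with `accuracy`, `sensitivity`, `specificity`, each a
#'   list holding `estimate` and `ci` (`c(lower, upper)`).
#' @export
binaryMetrics <- function(cm) {
  cm <- cm[c("tp", "fn", "fp", "tn")]
  .stopIf(anyNA(cm), "cm must contain counts tp, fn, fp, tn")
  .stopIf(cm["tp"] + cm["fn"] == 0 || cm["tn"] + cm["fp"] == 0,
          "undefined metric: empty positive or negative stratum")
  n <- sum(cm)
  list(
    accuracy = list(
      estimate = unname((cm["tp"] + cm["tn"]) / n),
      ci = .wilson(cm["tp"] + cm["tn"], n)),
    sensitivity = list(
      estimate = unname(cm["tp"] / (cm["tp"] + cm["fn"])),
      ci = .wilson(cm["tp"], cm["tp"] + cm["fn"])),
    specificity = list(
      estimate = unname(cm["tn"] / (cm["tn"] + cm["fp"])),
      ci = .wilson(cm["tn"], cm["tn"] + cm["fp"]))
  )
}

# DeLong variance of the Mann-Whitney AUC via placement values.
.delongVar <- function(pos, neg) {
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (length(v10) > 1) var(v10) else 0
  s01 <- if (length(v01) > 1) var(v01) else 0
  s10 / length(pos) + s01 / length(neg)
}

#' ROC curve and AUC for left-eye scores
#'
#' Sweeps a threshold over the unique scores (an instance is called left
#' iff `P1 >= t`), yielding the ROC points; the area under this curve
#' equals the Mann-Whitney probability that a random left-eye score exceeds
#' a random right-eye score, with ties counting one half. The 95%
#' confidence interval uses the DeLong variance estimator.
#'
#' @param scores Numeric vector of left-eye probabilities `P1`.
#' @param truths Character vector of `"left"` / `"right"` truths; both
#'   classes must be present.
#' @return A list with `auc`, `ci` (`c(lower, upper)`) and `points` (a
#'   `data.frame` of `fpr`, `tpr`, from (0, 0) to (1, 1)).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.85, 0.1),
#'        c("left", "left", "right", "right"))$auc   # 0.75
#' @export
rocAuc <- function(scores, truths) {
  .stopIf(length(scores) != length(truths),
          "scores and truths must have equal length")
  pos <- scores[truths == .LEFT]
  neg <- scores[truths == .RIGHT]
  .stopIf(!length(pos) || !length(neg),
          "undefined metric: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)), 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  se <- sqrt(.delongVar(pos, neg))
  z <- qnorm(0.975)
  list(auc = auc,
       ci = c(max(0, auc - z * se), min(1, auc + z * se)),
       points = data.frame(fpr = fpr, tpr = tpr))
}

#' Build the full evaluation report
#'
#' Label metrics use the 0.5 threshold with the left-eye tie-break (the
#' same rule as [predictLaterality()]); raw counts are always retained so
#' nothing is lost to rounding.
#'
#' @param scores Numeric vector of left-eye probabilities `P1`.
#' @param truths Character vector of `"left"` / `"right"` truths.
#' @return An [EvalReport-class].
#' @export
evalReport <- function(scores, truths) {
  pred <- ifelse(scores >= 0.5, .LEFT, .RIGHT)
  cm <- confusionCounts(pred, truths)
  bm <- binaryMetrics(cm)
  roc <- rocAuc(scores, truths)
  new("EvalReport", confusion = as.integer(cm) |> setNames(names(cm)),
      accuracy = bm$accuracy$estimate, accuracyCI = bm$accuracy$ci,
      sensitivity = bm$sensitivity$estimate,
      sensitivityCI = bm$sensitivity$ci,
      specificity = bm$specificity$estimate,
      specificityCI = bm$specificity$ci,
      auc = roc$auc, aucCI = roc$ci, rocPoints = roc$points)
}

#' Evaluate a classifier on labelled images
#'
#' @param model A [FundusClassifier-class].
#' @param images List of [FundusImage-class] with metadata labels.
#' @return A list with `report` (an [EvalReport-class]) and `predictions`
#'   (the per-image `data.frame` from [predictBatch()]).
#' @export
evaluateClassifier <- function(model, images) {
  preds <- predictBatch(model, images)
  list(report = evalReport(preds$p_left, preds$truth), predictions = preds)
}

#' Serialise an evaluation report to JSON
#'
#' Estimates are rounded to 4 decimals in the JSON; the raw confusion
#' counts are included unrounded.
#'
#' @param report An [EvalReport-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  cm <- report@confusion
  out <- list(
    confusion = list(tp = cm["tp"], fn = cm["fn"], fp = cm["fp"],
                     tn = cm["tn"]),
    accuracy = round(report@accuracy, 4),
    accuracy_ci = round(report@accuracyCI, 4),
    sensitivity = round(report@sensitivity, 4),
    sensitivity_ci = round(report@sensitivityCI, 4),
    specificity = round(report@specificity, 4),
    specificity_ci = round(report@specificityCI, 4),
    auc = round(report@auc, 4),
    auc_ci = round(report@aucCI, 4),
    roc = report@rocPoints
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
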