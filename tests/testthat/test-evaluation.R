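# Confusion counts, Wilson intervals, ROC/AUC with DeLong interval.

test_that("confusion counts treat the left eye as positive", {
  cm <- confusionCounts(c("left", "left", "right", "right"),
                        c("left", "left", "right", "right"))
  expect_equal(cm, c(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  cm2 <- confusionCounts(c("right", "right"), c("left", "right"))
  expect_equal(cm2, c(tp = 0L, fn = 1L, fp = 0L, tn = 1L))
  expect_error(confusionCounts(character(0), character(0)), "non-empty")
  expect_error(confusionCounts("left", c("left", "right")), "equal length")
})

test_that("binary metrics reproduce hand-computed tables", {
  bm <- binaryMetrics(c(tp = 99, fn = 1, fp = 1, tn = 99))
  expect_equal(bm$sensitivity$estimate, 0.99)
  expect_equal(bm$specificity$estimate, 0.99)
  expect_equal(bm$accuracy$estimate, 0.99)
  bm2 <- binaryMetrics(c(tp = 1, fn = 0, fp = 0, tn = 1))
  expect_equal(bm2$sensitivity$estimate, 1)
  expect_equal(bm2$specificity$estimate, 1)
  # Wilson 95% interval for 50/100 (z = 1.96)
  bm3 <- binaryMetrics(c(tp = 50, fn = 50, fp = 50, tn = 50))
  expect_equal(bm3$sensitivity$estimate, 0.5)
  expect_equal(bm3$sensitivity$ci, c(0.4038, 0.5962), tolerance = 1e-3)
  expect_error(binaryMetrics(c(tp = 0, fn = 0, fp = 1, tn = 1)),
               "undefined")
  # intervals bracket the estimates
  for (nm in c("accuracy", "sensitivity", "specificity")) {
    expect_lte(bm3[[nm]]$ci[1], bm3[[nm]]$estimate)
    expect_gte(bm3[[nm]]$ci[2], bm3[[nm]]$estimate)
  }
})

test_that("AUC matches its closed-form cases", {
  sep <- rocAuc(c(0.9, 0.8, 0.2, 0.1), c("left", "left", "right", "right"))
  expect_equal(sep$auc, 1)
  tied <- rocAuc(rep(0.5, 6), rep(c("left", "right"), 3))
  expect_equal(tied$auc, 0.5)
  ex <- rocAuc(c(0.9, 0.8, 0.85, 0.1), c("left", "left", "right", "right"))
  expect_equal(ex$auc, 0.75)   # 3 wins out of 4 pairs, no ties
  expect_error(rocAuc(c(0.1, 0.2), c("left", "left")), "both classes")
})

test_that("the ROC sweep starts at (0,0), ends at (1,1), and is monotone", {
  set.seed(10)
  scores <- round(runif(60), 2)
  truths <- sample(c("left", "right"), 60, replace = TRUE,
                   prob = c(0.4, 0.6))
  roc <- rocAuc(scores, truths)
  pts <- roc$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(11)
  for (rep in 1:5) {
    scores <- runif(80)
    truths <- sample(c("left", "right"), 80, replace = TRUE)
    a <- rocAuc(scores, truths)$auc
    b <- rocAuc(qlogis(scores * 0.98 + 0.01), truths)$auc
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("label-swap duality mirrors the evaluation surface", {
  set.seed(12)
  scores <- round(runif(50), 1)   # force ties
  truths <- sample(c("left", "right"), 50, replace = TRUE)
  a <- rocAuc(scores, truths)$auc
  swapped <- ifelse(truths == "left", "right", "left")
  b <- rocAuc(1 - scores, swapped)$auc
  expect_equal(a, b, tolerance = 1e-12)
  bmA <- binaryMetrics(confusionCounts(
    ifelse(scores >= 0.5, "left", "right"), truths))
  bmB <- binaryMetrics(confusionCounts(
    ifelse(1 - scores > 0.5, "left", "right"), swapped))
  expect_equal(bmA$sensitivity$estimate, bmB$specificity$estimate)
  expect_equal(bmA$specificity$estimate, bmB$sensitivity$estimate)
})

test_that("the DeLong interval agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (rep in 1:4) {
    n <- 120
    truths <- sample(c("left", "right"), n, replace = TRUE)
    scores <- runif(n) + 0.6 * (truths == "left")
    mine <- rocAuc(scores, truths)
    ref <- pROC::roc(response = factor(truths, c("right", "left")),
                     predictor = scores, quiet = TRUE,
                     direction = "<")
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(mine$ci, ci[c(1, 3)], tolerance = 1e-6)
  }
})

test_that("reports assemble and serialise every component", {
  set.seed(14)
  truths <- rep(c("left", "right"), each = 40)
  scores <- c(runif(40, 0.4, 1), runif(40, 0, 0.6))
  rep_ <- evalReport(scores, truths)
  expect_s4_class(rep_, "EvalReport")
  cm <- rep_@confusion
  expect_equal(sum(cm), 80L)
  expect_equal(rep_@accuracy, (cm["tp"] + cm["tn"]) / 80,
               ignore_attr = TRUE)
  f <- tempfile(fileext = ".json")
  writeEvalReport(rep_, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$confusion$tp, as.integer(cm["tp"]))
  expect_equal(j$auc, round(rep_@auc, 4))
  expect_equal(length(j$roc), nrow(rep_@rocPoints))
})
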