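test_that("AUC equals normalized pair counting", {
  r <- rocAuc(c(0.1, 0.4, 0.35, 0.8), c("A", "A", "B", "B"))
  expect_equal(r$auc, 0.75)                 # 3 of 4 pairs concordant

  # perfect separation and complete ties
  expect_equal(rocAuc(c(1, 1, 0, 0), c("B", "B", "A", "A"))$auc, 1.0)
  expect_equal(rocAuc(rep(0.5, 6), rep(c("A", "B"), 3))$auc, 0.5)

  set.seed(14)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    labels <- c("A", "B", sample(c("A", "B"), n - 2, replace = TRUE))
    scores <- if (i %% 2) runif(n) else round(runif(n), 1)  # with ties
    expect_equal(rocAuc(scores, labels)$auc,
                 bruteForceAuc(scores, labels), tolerance = 1e-12)
  }
  expect_error(rocAuc(runif(5), rep("B", 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(6)
  scores <- runif(50)
  labels <- sample(c("A", "B"), 50, replace = TRUE, prob = c(0.6, 0.4))
  a0 <- rocAuc(scores, labels)$auc
  expect_equal(rocAuc(exp(3 * scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(rocAuc(rank(scores), labels)$auc, a0, tolerance = 1e-12)
})

test_that("ROC curve points are monotone and anchored", {
  set.seed(8)
  r <- rocAuc(runif(40), sample(c("A", "B"), 40, replace = TRUE))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(19)
  scores <- round(runif(80), 2)
  labels <- sample(c("A", "B"), 80, replace = TRUE)
  ours <- rocAuc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("A", "B"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion counts and metric identities are exact", {
  cm <- confusionCounts(c("B", "A", "B"), c("B", "B", "B"))
  expect_identical(cm@tp, 2L); expect_identical(cm@fn, 1L)

  allRight <- confusionCounts(rep("B", 4), rep("B", 4))
  expect_identical(allRight@fp + allRight@fn, 0L)

  allWrong <- confusionCounts(rep("A", 6), rep("B", 6))
  expect_identical(allWrong@tp, 0L)
  expect_identical(allWrong@fn, 6L)

  # hand table: TP 9, FN 1, TN 23, FP 2
  cm <- new("ConfusionMatrix", tp = 9L, fn = 1L, tn = 23L, fp = 2L)
  rep <- metricReport(cm, auc = 0.97)
  expect_equal(rep$recall_sensitivity, 0.9)
  expect_equal(rep$specificity, 0.92)
  expect_equal(rep$accuracy, 32 / 35)
  expect_equal(rep$precision, 9 / 11)
  expect_equal(rep$f1,
               2 * rep$precision * rep$recall_sensitivity /
                 (rep$precision + rep$recall_sensitivity),
               tolerance = 1e-9)

  expect_error(confusionCounts(c("A", "B"), c("A")), "equal length")

  # degenerate denominators give NA, not errors
  none <- metricReport(new("ConfusionMatrix", tp = 0L, fn = 0L,
                           tn = 5L, fp = 0L))
  expect_true(is.na(none$recall_sensitivity))
})

test_that("confusion matrices render to a shaded PNG", {
  cm <- new("ConfusionMatrix", tp = 9L, fn = 1L, tn = 23L, fp = 2L)
  path <- withr::local_tempfile(fileext = ".png")
  img <- renderConfusionMatrix(cm, path)
  expect_true(file.exists(path))
  expect_identical(dim(img), c(128L, 128L))
  # the largest count (TN) is the darkest cell
  expect_lt(img[100, 100], img[30, 30])
})

test_that("fold aggregation uses mean and sample SD", {
  reports <- list(data.frame(auc = 0.9, accuracy = 0.8),
                  data.frame(auc = 1.0, accuracy = 0.9))
  agg <- aggregateFolds(reports)
  expect_equal(agg["mean", "auc"], 0.95)
  expect_equal(agg["sd", "auc"], sd(c(0.9, 1.0)))
  expect_equal(agg["sd", "auc"], 0.0707, tolerance = 1e-3)

  same <- aggregateFolds(list(data.frame(auc = 0.9),
                              data.frame(auc = 0.9),
                              data.frame(auc = 0.9)))
  expect_equal(same["sd", "auc"], 0)

  expect_error(aggregateFolds(list()), "no fold")
  expect_error(aggregateFolds(list(data.frame(auc = 1))), "at least 2")

  txt <- formatMetricTable(agg)
  expect_match(txt["auc"], "0.950 \\(SD 0.071\\)")
})
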