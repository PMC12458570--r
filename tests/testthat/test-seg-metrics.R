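test_that("confusion metrics match hand-computed values and conventions", {
  pred <- matrix(c(1, 1, 0, 0), 2, byrow = TRUE)
  truth <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE)
  m <- confusionMetrics(pred, truth)
  expect_equal(unname(m[c("iou", "dsc", "acc", "sen", "spe")]),
               c(1 / 2, 2 / 3, 3 / 4, 1, 2 / 3))

  t1 <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  ident <- confusionMetrics(t1, t1)
  expect_equal(unname(ident), rep(1, 5))

  a <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  b <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2)
  dis <- confusionMetrics(a, b)
  expect_equal(unname(dis[c("iou", "dsc")]), c(0, 0))

  empty <- matrix(FALSE, 3, 3)
  both <- confusionMetrics(empty, empty)
  expect_equal(unname(both[c("iou", "dsc", "acc", "sen")]), c(1, 1, 1, 1))

  expect_error(confusionMetrics(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "same shape")
})

test_that("metrics agree with exhaustive computation on random 5x5 masks", {
  set.seed(31)
  checked <- 0
  for (rep in 1:200) {
    p <- matrix(stats::runif(25) < 0.4, 5)
    q <- matrix(stats::runif(25) < 0.4, 5)
    cm <- confusionMetrics(p, q)
    bc <- bruteConfusion(p, q)
    un <- bc["tp"] + bc["fp"] + bc["fn"]
    expect_equal(cm[["iou"]], if (un == 0) 1 else unname(bc["tp"] / un))
    expect_equal(cm[["acc"]], unname((bc["tp"] + bc["tn"]) / 25))
    if (bc["tp"] + bc["fn"] > 0)
      expect_equal(cm[["sen"]], unname(bc["tp"] / (bc["tp"] + bc["fn"])))
    if (bc["tn"] + bc["fp"] > 0)
      expect_equal(cm[["spe"]], unname(bc["tn"] / (bc["tn"] + bc["fp"])))
    expect_equal(cm[["dsc"]], 2 * cm[["iou"]] / (1 + cm[["iou"]]))

    if (any(p) && any(q)) {
      bp <- bruteBoundary(p); bq <- bruteBoundary(q)
      dPQ <- bruteDirected(bp, bq); dQP <- bruteDirected(bq, bp)
      expect_equal(hausdorffDistance(p, q), max(max(dPQ), max(dQP)))
      expect_equal(meanAbsDeviation(p, q), mean(dPQ))
      expect_lte(meanAbsDeviation(p, q),
                 hausdorffDistance(p, q) + 1e-12)
      checked <- checked + 1
    }
    # symmetry under simultaneous transposition
    expect_equal(confusionMetrics(t(p), t(q)), cm)
  }
  expect_gt(checked, 100)
})

test_that("AUROC behaves as a rank statistic", {
  tr <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(aurocFromMap(matrix(as.numeric(tr), 2), tr), 1)
  expect_equal(aurocFromMap(matrix(1 - as.numeric(tr), 2), tr), 0)

  set.seed(12)
  mp <- matrix(stats::runif(1e4), 100)
  lab <- matrix(stats::runif(1e4) < 0.5, 100)
  a <- aurocFromMap(mp, lab)
  expect_lt(abs(a - 0.5), 0.02)
  expect_equal(aurocFromMap(exp(3 * mp), lab), a)    # monotone invariance

  skip_if_not_installed("pROC")
  pr <- as.numeric(pROC::auc(pROC::roc(as.vector(lab), as.vector(mp),
                                       quiet = TRUE, direction = "<")))
  expect_equal(a, pr, tolerance = 1e-10)
})

test_that("AUROC requires both classes", {
  expect_error(aurocFromMap(matrix(1, 4, 4), matrix(TRUE, 4, 4)),
               "both classes")
})

test_that("boundary distances: points, concentric squares, empty masks", {
  a <- matrix(FALSE, 5, 8); a[2, 3] <- TRUE
  b <- matrix(FALSE, 5, 8); b[2, 6] <- TRUE
  expect_equal(hausdorffDistance(a, b), 3)
  expect_equal(meanAbsDeviation(a, b), 3)
  expect_equal(hausdorffDistance(b, b), 0)
  expect_equal(meanAbsDeviation(b, b), 0)

  truth <- matrix(FALSE, 11, 11); truth[4:8, 4:8] <- TRUE
  pred <- matrix(FALSE, 11, 11); pred[2:10, 2:10] <- TRUE
  bp <- bruteBoundary(pred); bt <- bruteBoundary(truth)
  expect_equal(meanAbsDeviation(pred, truth),
               mean(bruteDirected(bp, bt)))
  # corner pixels sit 2*sqrt(2) from the truth corner, so the mean
  # is slightly above the 2 px edge offset
  expect_lt(abs(meanAbsDeviation(pred, truth) - 2), 0.25)

  expect_error(hausdorffDistance(a, matrix(FALSE, 5, 8)), "empty")
  expect_error(meanAbsDeviation(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)),
               "empty")
})

test_that("batch evaluation returns one row per image plus summary rows", {
  set.seed(8)
  preds <- lapply(1:4, function(i) matrix(stats::runif(64) < 0.4, 8))
  truths <- lapply(1:4, function(i) matrix(stats::runif(64) < 0.4, 8))
  maps <- lapply(preds, function(p) matrix(stats::runif(64), 8))
  tab <- evaluateSegmentation(preds, truths, maps)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$image[5:6], c("mean", "sd"))
  expect_equal(tab$iou[5], mean(tab$iou[1:4]))
})
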