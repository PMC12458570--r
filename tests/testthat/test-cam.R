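test_that("threshold mask binarises relative to the map maximum", {
  expect_true(all(!thresholdMask(matrix(0, 4, 4), 0.5)))
  expect_true(all(thresholdMask(matrix(1, 4, 4), 0.5)))
  m <- matrix(c(0.2, 0.6, 0.9, 0.1), 2)
  expect_equal(thresholdMask(m, 0.5), m > 0.45)
  expect_equal(sum(thresholdMask(m, 0.5)), 2)   # exactly the 0.6 and 0.9 pixels
  expect_error(thresholdMask(m, 0), "between 0 and 1")
  expect_error(thresholdMask(m, 1), "between 0 and 1")
})

test_that("coverage score is the exact mask fraction and rotation-invariant", {
  expect_equal(coverageScore(matrix(FALSE, 5, 5)), 0)
  m <- matrix(FALSE, 100, 100); m[1:50, 1:50] <- TRUE
  expect_equal(coverageScore(m), 0.25)
  set.seed(3)
  r <- matrix(stats::runif(400) < 0.3, 20, 20)
  expect_equal(coverageScore(r), sum(r) / 400)
  expect_equal(coverageScore(t(r)), coverageScore(r))
  rot90 <- t(r)[ncol(r):1, ]
  expect_equal(coverageScore(rot90), coverageScore(r))
  expect_error(coverageScore(matrix(logical(0), 0, 0)), "empty")
})

test_that("Grad-CAM maps are normalised and localise the eardrum", {
  clf <- sharedBinaryClassifier()
  test <- generateShapesDataset(40, seed = 901)
  pres <- which(as.character(classLabels(test)) == "present")
  inMinusOut <- vapply(pres, function(i) {
    m <- camValues(gradCAM(clf, test@images[[i]], "present"))
    expect_true(all(m >= 0 & m <= 1))
    mean(m[test@masks[[i]]]) - mean(m[!test@masks[[i]]])
  }, numeric(1))
  expect_length(inMinusOut, 20)
  expect_gt(mean(inMinusOut), 0)
  expect_gt(mean(inMinusOut > 0), 0.8)

  # a head with zero weights for the class has zero feature gradients
  clf0 <- clf
  clf0@params$Wd[, 1L] <- 0
  expect_true(all(camValues(gradCAM(clf0, test@images[[pres[1]]], 1L)) == 0))

  expect_error(gradCAM(clf, test@images[[1]], 5L), "out of range")
  expect_error(gradCAM(clf, test@images[[1]], "wax"), "unknown class")
})

test_that("climbing reduces to Grad-CAM at T = 0 and is continuous in the step", {
  clf <- sharedBinaryClassifier()
  img <- generateFrame(randomFrameSpec(4242, c(64, 64),
                                       visibility = "full"))@image
  g <- gradCAM(clf, img, "present")
  a0 <- adversarialClimb(clf, img, "present",
                         climbingConfig(iterations = 0L))
  expect_identical(camValues(a0), camValues(g))

  aTiny <- adversarialClimb(clf, img, "present",
                            climbingConfig(eps = 1e-8, iterations = 5L))
  expect_equal(camValues(aTiny), camValues(g), tolerance = 1e-4)
})

test_that("climbing raises the target logit and expands the activated region", {
  clf <- sharedBinaryClassifier()
  test <- generateShapesDataset(20, seed = 902)
  pres <- which(as.character(classLabels(test)) == "present")
  stat <- t(vapply(pres, function(i) {
    a <- adversarialClimb(clf, test@images[[i]], "present",
                          climbingConfig(), details = TRUE)
    g <- gradCAM(clf, test@images[[i]], "present")
    c(up = attr(a, "logitT") >= attr(a, "logit0"),
      areaG = sum(thresholdMask(g, 0.5)),
      areaA = sum(thresholdMask(a, 0.5)))
  }, numeric(3)))
  expect_gte(mean(stat[, "up"]), 0.9)
  expect_gte(mean(stat[, "areaA"]), mean(stat[, "areaG"]))
})

test_that("binary-class refinement reduces correctly in its limits", {
  clf <- sharedBinaryClassifier()
  img <- generateFrame(randomFrameSpec(4243, c(64, 64),
                                       visibility = "full"))@image
  b0 <- bcAdvCAM(clf, img, climbingConfig(bcLambda = 0))
  a <- adversarialClimb(clf, img, "present", climbingConfig())
  expect_equal(camValues(b0), camValues(a))

  # identical class heads make both maps equal: full self-cancellation
  clfEq <- clf
  clfEq@params$Wd[, 1L] <- clfEq@params$Wd[, 2L]
  clfEq@params$bd[1L] <- clfEq@params$bd[2L]
  bEq <- bcAdvCAM(clfEq, img, climbingConfig(bcLambda = 1))
  expect_true(all(camValues(bEq) == 0))

  expect_error(bcAdvCAM(sharedViewClassifier(), img), "binary")
  expect_true(all(camValues(bcAdvCAM(clf, img)) >= 0))
})

test_that("refined masks overlap ground truth better than plain Grad-CAM", {
  clf <- sharedBinaryClassifier()
  test <- generateShapesDataset(16, seed = 903)
  pres <- which(as.character(classLabels(test)) == "present")
  iou <- function(map, truth)
    confusionMetrics(thresholdMask(map, 0.5), truth)[["iou"]]
  d <- t(vapply(pres, function(i) {
    c(g = iou(gradCAM(clf, test@images[[i]], "present"), test@masks[[i]]),
      b = iou(bcAdvCAM(clf, test@images[[i]]), test@masks[[i]]))
  }, numeric(2)))
  expect_gt(mean(d[, "b"]), mean(d[, "g"]))
})
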