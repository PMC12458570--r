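test_that("frame rendering is deterministic and geometrically faithful", {
  sp <- frameSpec(c(96, 96), fovRadius = 36, visibility = "full",
                  focusOffset = c(0, 0), textureSeed = 7)
  fr1 <- generateFrame(sp)
  fr2 <- generateFrame(sp)
  expect_identical(fr1@image, fr2@image)
  expect_true(all(fr1@image >= 0 & fr1@image <= 1))
  expect_lt(mean(fr1@image[!fr1@fovMask]), 0.1)
  expect_gt(mean(toGrayscale(fr1@image)[fr1@fovMask]), 0.3)
  expect_false(any(fr1@eardrumMask & !fr1@fovMask))

  # rasterised disk area vs analytic area, within 2%
  sp2 <- frameSpec(c(160, 160), fovRadius = 60, eardrumRadius = 30,
                   visibility = "full")
  fr <- generateFrame(sp2)
  expect_lt(abs(sum(fr@eardrumMask) - pi * 30^2) / (pi * 30^2), 0.02)
  expect_lt(abs(sum(fr@fovMask) - pi * 60^2) / (pi * 60^2), 0.02)
})

test_that("invalid or inconsistent geometry is rejected", {
  expect_error(frameSpec(c(64, 64), fovCenter = c(10, 32), fovRadius = 30),
               "does not fit")
  expect_error(frameSpec(c(96, 96), fovRadius = 30, visibility = "partial",
                         eardrumCenter = c(47.5, 47.5), eardrumRadius = 10),
               "clipped")
  expect_error(frameSpec(c(96, 96), fovRadius = 30, visibility = "full",
                         eardrumCenter = c(70, 47.5), eardrumRadius = 20),
               "entirely inside")
  expect_error(frameSpec(c(96, 96), blurSigma = -1), "blurSigma")
})

test_that("visibility semantics: none draws nothing, partial clips 25-75%", {
  frN <- generateFrame(randomFrameSpec(3, visibility = "none"))
  expect_true(all(!frN@eardrumMask))
  for (s in 4:9) {
    sp <- randomFrameSpec(s, visibility = "partial")
    fr <- generateFrame(sp)
    insideFrac <- sum(fr@eardrumMask) / (pi * sp@eardrumRadius^2)
    expect_gt(insideFrac, 0.2)
    expect_lt(insideFrac, 0.8)
  }
})

test_that("sharpness energy inside the FOV strictly decreases with blur", {
  logVar <- vapply(c(0, 1, 2, 4, 8), function(sg) {
    fr <- generateFrame(frameSpec(c(160, 160), fovRadius = 60,
                                  visibility = "full", blurSigma = sg,
                                  textureSeed = 21))
    g <- toGrayscale(fr@image)
    lap <- otomif:::.laplacian(otomif:::.gaussBlurMat(g, 1))
    stats::var(as.vector(lap[fr@fovMask]))
  }, numeric(1))
  expect_true(all(diff(logVar) < 0))
})

test_that("video containers: count, sidecar, lossless round trip, best flag", {
  vid <- designBestFrameVideo(seed = 2, n = 10, imageSize = c(96, 96))
  path <- file.path(tempdir(), "vid10.tiff")
  out <- generateVideo(vid$specs, path, bestIndex = vid$bestIndex)
  expect_equal(nrow(out$truth), 10)
  expect_equal(sum(out$truth$designed_best), 1)
  expect_equal(out$truth$frame_index[out$truth$designed_best], vid$bestIndex)
  expect_true(file.exists(out$sidecar))

  fr <- readFrames(path)
  expect_equal(length(fr), 10)
  img0 <- round(generateFrame(vid$specs[[1]])@image * 255) / 255
  expect_equal(max(abs(fr[[1]] - img0)), 0)

  dirp <- file.path(tempdir(), "vid_png")
  generateVideo(vid$specs[1:3], dirp, format = "png")
  fr2 <- readFrames(dirp)
  expect_equal(length(fr2), 3)
  expect_equal(max(abs(fr2[[2]] -
                       round(generateFrame(vid$specs[[2]])@image * 255) / 255)), 0)

  expect_error(generateVideo(list(vid$specs[[1]],
                                  randomFrameSpec(1, c(64, 64))), path),
               "same image size")
})

test_that("shapes dataset is balanced, masked, and reproducible", {
  ds <- generateShapesDataset(100, seed = 3)
  tb <- table(classLabels(ds))
  expect_equal(unname(tb[["absent"]]), 50)
  expect_equal(unname(tb[["present"]]), 50)
  pres <- which(as.character(classLabels(ds)) == "present")
  expect_true(all(vapply(ds@masks[pres], sum, numeric(1)) > 0))
  absent <- which(as.character(classLabels(ds)) == "absent")
  expect_true(all(vapply(ds@masks[absent], sum, numeric(1)) == 0))

  ds2 <- generateShapesDataset(100, seed = 3)
  expect_identical(ds@images, ds2@images)

  ds3 <- generateShapesDataset(7, seed = 1)
  tb3 <- table(classLabels(ds3))
  expect_lte(abs(tb3[[1]] - tb3[[2]]), 1)

  dsv <- generateShapesDataset(9, seed = 2, classes = "view")
  expect_setequal(levels(classLabels(dsv)), c("none", "partial", "full"))
  expect_lte(diff(range(table(classLabels(dsv)))), 1)

  expect_error(generateShapesDataset(1, seed = 1), "at least 2")
})
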