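test_that("edge energy vanishes on constant frames and scales with step height", {
  fov <- new("FovCircle", x = 31, y = 31, r = 20, deltaL = 1)
  expect_true(all(edgeEnergy(matrix(0.5, 64, 64), fov) == 0))

  mkStep <- function(h) {
    m <- matrix(0.2, 64, 64); m[, 33:64] <- 0.2 + h; m
  }
  e1 <- max(abs(edgeEnergy(mkStep(0.2), fov)))
  e2 <- max(abs(edgeEnergy(mkStep(0.4), fov)))
  expect_equal(e1, 0.2)         # unit-step response of the scaled kernel
  expect_equal(e2 / e1, 2)      # proportional to the step height

  expect_error(edgeEnergy(matrix(0.5, 10, 10),
                          new("FovCircle", x = 2, y = 2, r = 2.5,
                              deltaL = 1)),
               "9 px")
})

test_that("blurring shrinks the tail of the edge-energy sample", {
  fov <- new("FovCircle", x = 79.5, y = 79.5, r = 60, deltaL = 1)
  g0 <- toGrayscale(generateFrame(frameSpec(c(160, 160), fovRadius = 60,
                                            visibility = "full",
                                            textureSeed = 33))@image)
  g4 <- toGrayscale(generateFrame(frameSpec(c(160, 160), fovRadius = 60,
                                            visibility = "full",
                                            blurSigma = 4,
                                            textureSeed = 33))@image)
  q0 <- stats::quantile(abs(edgeEnergy(g0, fov)), 0.99)
  q4 <- stats::quantile(abs(edgeEnergy(g4, fov)), 0.99)
  expect_lt(q4, q0)
})

test_that("the mixture fit recovers the wider component's spread", {
  set.seed(11)
  pick <- stats::runif(10000) < 0.5
  z <- ifelse(pick, stats::rnorm(10000, 0, 0.01), stats::rnorm(10000, 0, 0.2))
  fit <- fitEdgeGmm(z, seed = 1)
  expect_lt(abs(sigmaMax(fit) - 0.2) / 0.2, 0.10)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-6)
  expect_false(fit@degenerate)

  # independent EM implementation as cross-check
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust resolves this in the caller
  mc <- mclust::Mclust(z, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sigmaMax(fit), sqrt(max(mc$parameters$variance$sigmasq)),
               tolerance = 0.05)
})

test_that("mixture fit degenerate and collapsed cases", {
  z1 <- stats::rnorm(5000, 0, 0.1)
  set.seed(21); z1 <- stats::rnorm(5000, 0, 0.1)
  fit1 <- fitEdgeGmm(z1, seed = 1)
  expect_lt(abs(sigmaMax(fit1) - 0.1) / 0.1, 0.15)

  fit0 <- fitEdgeGmm(rep(0.3, 100), seed = 1)
  expect_true(fit0@degenerate)
  expect_equal(sigmaMax(fit0), 0)

  expect_error(fitEdgeGmm(stats::rnorm(30)), "at least 50")
  expect_error(fitEdgeGmm(c(rep(0, 60), Inf)), "finite")
})

test_that("blur score is the guarded ratio of spread to contrast", {
  expect_equal(blurScore(0, 0.5), 0)
  expect_equal(blurScore(0.2, 0.1, eps = 1e-6), 0.2 / (0.1 + 1e-6))
  expect_equal(blurScore(0.3, 0.2) / blurScore(0.3, 0.4), 2,
               tolerance = 1e-4)
  fit <- fitEdgeGmm(c(stats::rnorm(100, 0, 0.05)), seed = 1)
  expect_equal(blurScore(fit, 0.2), fit@sigmaMax / (0.2 + 1e-6))
})

test_that("FOV detection recovers synthetic circles and rejects flat frames", {
  errs <- vapply(1:12, function(s) {
    sp <- randomFrameSpec(s + 500L, visibility = "full")
    f <- detectFov(toGrayscale(generateFrame(sp)@image))
    c(sqrt(sum((fovCenter(f) - sp@fovCenter)^2)),
      abs(fovRadius(f) - sp@fovRadius))
  }, numeric(2))
  expect_true(all(errs[1, ] <= 2))
  expect_true(all(errs[2, ] <= 3))

  expect_error(detectFov(matrix(0.5, 120, 120)), class = "otomifNoFov")
})

test_that("the circle with the true lightness step beats a decoy ring", {
  g <- matrix(0.05, 160, 160)
  d2 <- otomif:::.dist2Grid(160, 160, 79.5, 79.5)
  g[d2 <= 48^2] <- 0.8
  g[d2 > 58^2 & d2 <= 61^2] <- 0.95   # bright decoy ring, no net step
  f <- detectFov(g)
  expect_lt(abs(fovRadius(f) - 48), 3)
  expect_lt(sqrt(sum((fovCenter(f) - c(79.5, 79.5))^2)), 3)

  # invariance under global intensity scaling
  for (fac in c(0.5, 0.1)) {
    f2 <- detectFov(g * fac)
    expect_equal(fovCenter(f2), fovCenter(f))
    expect_equal(fovRadius(f2), fovRadius(f))
  }
})

test_that("focus point equals an exhaustive argmax of the sharpness response", {
  # independent oracle: direct O(n^2 k^2) Gaussian convolution with
  # replicated edges, 4-neighbour Laplacian, squared, full scan with the
  # smallest-row-then-column tie-break
  oracleFocus <- function(gray, sigma = 2) {
    r <- max(1, ceiling(3 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
    K <- outer(k, k)
    h <- nrow(gray); w <- ncol(gray)
    at <- function(m, i, j) m[min(max(i, 1), h), min(max(j, 1), w)]
    sm <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w) {
      acc <- 0
      for (a in -r:r) for (b in -r:r)
        acc <- acc + K[a + r + 1, b + r + 1] * at(gray, i + a, j + b)
      sm[i, j] <- acc
    }
    S <- matrix(0, h, w)
    for (i in 1:h) for (j in 1:w)
      S[i, j] <- (at(sm, i + 1, j) + at(sm, i - 1, j) + at(sm, i, j + 1) +
                  at(sm, i, j - 1) - 4 * sm[i, j])^2
    best <- c(NA, NA); bv <- -Inf
    for (i in 1:h) for (j in 1:w)
      if (S[i, j] > bv) { bv <- S[i, j]; best <- c(j - 1, i - 1) }
    best
  }
  set.seed(5)
  for (rep in 1:3) {
    g <- matrix(stats::runif(32 * 32), 32, 32)
    fp <- detectFocusPoint(g)
    expect_equal(c(fp$x, fp$y), oracleFocus(g))
  }
  flat <- detectFocusPoint(matrix(0.7, 16, 16))
  expect_true(flat$flat)
  expect_equal(c(flat$x, flat$y), c(0, 0))
})

test_that("the sharp patch is localised amid heavy blur", {
  hits <- vapply(1:5, function(s) {
    sp <- randomFrameSpec(s + 7000L, visibility = "full", blurSigma = 6,
                          focus = "random")
    fr <- generateFrame(sp)
    fp <- detectFocusPoint(toGrayscale(fr@image))
    tx <- sp@fovCenter + sp@focusOffset
    sqrt((fp$x - tx[1])^2 + (fp$y - tx[2])^2) <= sp@patchRadius
  }, logical(1))
  expect_true(all(hits))
})

test_that("focus score is the clamped centre distance margin", {
  fov <- new("FovCircle", x = 50, y = 50, r = 10, deltaL = 1)
  expect_equal(focusScore(fov, c(50, 50)), 10)
  expect_equal(focusScore(fov, c(50, 60)), 0)   # on the rim
  expect_equal(focusScore(fov, c(53, 54)), 5)   # 3-4-5 triangle
  expect_equal(focusScore(fov, c(70, 70)), 0)   # outside, clamped

  # invariant under rotation of the focus point about the centre
  th <- seq(0, 2 * pi, length.out = 9)
  vals <- vapply(th, function(t)
    focusScore(fov, c(50 + 4 * cos(t), 50 + 4 * sin(t))), numeric(1))
  expect_equal(vals, rep(6, 9))
})

test_that("final blur score multiplies its factors and orders frame pairs", {
  expect_equal(finalBlurScore(0, 7), 0)
  expect_equal(finalBlurScore(3, 0), 0)
  expect_equal(finalBlurScore(2, 5), 10)

  spSharp <- frameSpec(c(160, 160), fovRadius = 60, visibility = "full",
                       focusOffset = c(0, 0), textureSeed = 13)
  sharpImg <- generateFrame(spSharp)@image
  blurImg <- sharpImg                      # uniformly defocused copy
  for (ch in 1:3)
    blurImg[, , ch] <- otomif:::.gaussBlurMat(sharpImg[, , ch], 4)
  cSharp <- clarityScore(sharpImg)
  cBlur <- clarityScore(blurImg)
  expect_gt(finalBlur(cSharp), finalBlur(cBlur))
  expect_equal(cSharp@sBlf, cSharp@sBl * cSharp@sF)

  # graceful no-FOV degradation
  dark <- clarityScore(array(0.5, c(120, 120, 3)))
  expect_true(dark@noFov)
  expect_equal(finalBlur(dark), 0)
})

test_that("blur score decreases across increasing blur levels", {
  mono <- vapply(1:5, function(s) {
    sb <- vapply(c(0, 2, 8), function(sg) {
      sp <- randomFrameSpec(s + 3000L, visibility = "full", blurSigma = sg)
      clarityScore(generateFrame(sp)@image, seed = 1L)@sBl
    }, numeric(1))
    all(diff(sb) < 0)
  }, logical(1))
  expect_true(all(mono))
})
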