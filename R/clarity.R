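# Image-clarity assessment: the signed edge-energy distribution inside the
# otoscope field of view, summarised by a 2-component Gaussian mixture whose
# wider component separates sharp frames (long-tailed edge energies) from
# blurry ones (energies concentrated near zero); circular-FOV detection by a
# Hough-style gradient vote refined by the interior-vs-annulus lightness
# change; and a Laplacian-of-Gaussian focus point scored by its centrality.

#' Signed edge-energy sample inside the field of view
#'
#' Convolves the luminance image with 3x3 Sobel kernels (scaled so a unit
#' step edge peaks at 1) and pools the signed horizontal and vertical
#' responses of all pixels whose full 3x3 neighbourhood lies inside the FOV
#' circle. The sign carries the edge direction, so the pooled sample is
#' zero-centred and its spread measures edge strength.
#'
#' @param gray luminance matrix in \[0,1\].
#' @param fov a [FovCircle-class].
#' @return numeric vector of signed edge responses (both orientations
#'   pooled), with attribute \code{sourcePixelCount}.
#' @seealso [fitEdgeGmm()], [blurScore()]
#' @export
edgeEnergy <- function(gray, fov) {
  .assertGray(gray)
  stopifnot(is(fov, "FovCircle"))
  h <- nrow(gray); w <- ncol(gray)
  # sample the inner 72% of the radius: this keeps the 3x3 kernel support
  # away from the rim and, on blurred frames, from the rim's smeared
  # dark-to-bright transition, which would otherwise dominate the tail
  inner <- .dist2Grid(h, w, fov@x, fov@y) < (pmin(0.72 * fov@r, fov@r - 2))^2
  if (sum(inner) < 9L)
    stop("FOV interior smaller than 9 px; no edge-energy sample",
         call. = FALSE)
  g <- .sobel(gray)
  out <- c(g$gx[inner], g$gy[inner])
  attr(out, "sourcePixelCount") <- sum(inner)
  out
}

# log-sum-exp of two columns
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Fit a two-component Gaussian mixture to edge energies
#'
#' EM fit of a 1-D two-component Gaussian mixture, initialised from a seeded
#' 2-means clustering, run to convergence of the log-likelihood (tolerance
#' 1e-6, at most 100 iterations). The statistic of interest is
#' \code{sigmaMax}, the standard deviation of the wider component,
#' regardless of its weight. A constant sample (or a collapsed fit) returns
#' \code{sigmaMax = 0} with the degenerate flag set.
#'
#' @param values numeric vector of at least 50 edge responses.
#' @param seed integer seed for the initialisation.
#' @param maxIter,tol EM stopping rule.
#' @return a [GmmFit-class].
#' @export
fitEdgeGmm <- function(values, seed = 1L, maxIter = 100L, tol = 1e-6) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  n <- length(values)
  if (n < 50L)
    stop("need at least 50 edge-energy values, got ", n, call. = FALSE)
  if (stats::sd(values) < 1e-12) {
    return(new("GmmFit", means = rep(mean(values), 2L), sds = c(0, 0),
               weights = c(0.5, 0.5), sigmaMax = 0, degenerate = TRUE,
               loglik = NA_real_, iterations = 0L))
  }
  .withSeed(seed, {
    km <- suppressWarnings(stats::kmeans(values, centers = 2L, nstart = 3L))
    mu <- as.numeric(km$centers)
    sg <- vapply(1:2, function(k) {
      v <- values[km$cluster == k]
      max(stats::sd(v), 1e-8)
    }, numeric(1))
    sg[is.na(sg)] <- stats::sd(values)
    wt <- pmax(tabulate(km$cluster, 2L) / n, 1e-3)
    wt <- wt / sum(wt)

    ll <- -Inf; iter <- 0L
    floorSd <- 1e-8
    repeat {
      iter <- iter + 1L
      la <- log(wt[1L]) + stats::dnorm(values, mu[1L], sg[1L], log = TRUE)
      lb <- log(wt[2L]) + stats::dnorm(values, mu[2L], sg[2L], log = TRUE)
      norm <- .lse2(la, lb)
      newll <- sum(norm)
      r1 <- exp(la - norm)
      n1 <- sum(r1); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(r1 * values) / n1, sum((1 - r1) * values) / n2)
      sg <- c(sqrt(sum(r1 * (values - mu[1L])^2) / n1),
              sqrt(sum((1 - r1) * (values - mu[2L])^2) / n2))
      sg <- pmax(sg, floorSd)
      wt <- c(n1, n2) / n
      if (is.finite(ll) && abs(newll - ll) < tol) { ll <- newll; break }
      if (iter >= maxIter) { ll <- newll; break }
      ll <- newll
    }
    new("GmmFit", means = mu, sds = sg, weights = wt,
        sigmaMax = max(sg), degenerate = max(sg) <= floorSd * 10,
        loglik = ll, iterations = iter)
  })
}

#' Blur score from the edge-energy mixture
#'
#' \deqn{S_{bl} = \sigma_{max} / (C_p + \epsilon)} where \eqn{\sigma_{max}}
#' is the wider-component standard deviation of the edge-energy mixture and
#' \eqn{C_p} the image contrast. Larger values mean a clearer frame: sharp
#' frames have long-tailed edge energies (large \eqn{\sigma_{max}}) relative
#' to their overall contrast.
#'
#' @param fit a [GmmFit-class], or directly a numeric \eqn{\sigma_{max}}.
#' @param contrast \eqn{C_p \ge 0}, the RMS contrast of the frame inside the
#'   FOV.
#' @param eps small positive guard against division by zero (default 1e-6).
#' @return numeric(1), non-negative.
#' @export
blurScore <- function(fit, contrast, eps = 1e-6) {
  sMax <- if (is(fit, "GmmFit")) fit@sigmaMax else as.numeric(fit)
  stopifnot(is.finite(sMax), sMax >= 0, is.finite(contrast), contrast >= 0,
            eps > 0)
  sMax / (contrast + eps)
}

# Mean lightness inside the circle and in the clipped exterior annulus of
# width deltaR; returns their absolute difference (NA when either region is
# empty within the image).
.deltaL <- function(gray, cx, cy, r, deltaR) {
  d2 <- .dist2Grid(nrow(gray), ncol(gray), cx, cy)
  interior <- d2 <= r^2
  annulus <- d2 > r^2 & d2 <= (r + deltaR)^2
  if (!any(interior) || !any(annulus)) return(NA_real_)
  abs(mean(gray[interior]) - mean(gray[annulus]))
}

#' Detect the otoscope field-of-view circle
#'
#' Candidate circles come from a Hough-style accumulator: Sobel edge pixels
#' vote, along their gradient direction, for centres at each radius in the
#' search range; each radius contributes its strongest accumulator peak.
#' Every candidate is then scored by the lightness change \eqn{\Delta L} --
#' the absolute difference between the mean luminance of the circle interior
#' and of the width-\code{deltaR} exterior annulus (clipped to the image) --
#' and the candidate with the largest \eqn{\Delta L} wins, after a local
#' refinement of centre (+/-2 px) and radius (+/-2 px) under the same
#' criterion.
#'
#' Edge selection is relative to the strongest gradient in the frame, so
#' detection is invariant under global intensity scaling.
#'
#' @param gray luminance matrix in \[0,1\].
#' @param radiusRange numeric(2), searched radius range as fractions of
#'   \code{min(nrow, ncol)}; default \code{c(0.25, 0.60)}.
#' @param deltaR exterior annulus width in px.
#' @param radiusStep step (px) of the radius grid.
#' @return a [FovCircle-class]. When the image has no gradient structure or
#'   no candidate attains a positive \eqn{\Delta L}, an error of class
#'   \code{otomifNoFov} is signalled; pipeline callers treat it as "no FOV"
#'   and give the frame a final blur score of 0.
#' @export
detectFov <- function(gray, radiusRange = c(0.25, 0.60), deltaR = 5,
                      radiusStep = 2) {
  .assertGray(gray)
  h <- nrow(gray); w <- ncol(gray)
  noFov <- function(msg) stop(structure(
    class = c("otomifNoFov", "error", "condition"),
    list(message = msg, call = sys.call(-1))))

  g <- .sobel(.gaussBlurMat(gray, 1))
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx <= 0) noFov("no gradient structure: no circular FOV candidate")
  edge <- which(mag > 0.25 * mx)
  if (length(edge) < 30L) noFov("too few edge pixels for a circle candidate")
  if (length(edge) > 4000L)
    edge <- edge[order(mag[edge], decreasing = TRUE)[1:4000]]
  ey <- (edge - 1L) %% h          # 0-based row (y)
  ex <- (edge - 1L) %/% h         # 0-based col (x)
  ux <- g$gx[edge] / mag[edge]
  uy <- g$gy[edge] / mag[edge]

  radii <- seq(radiusRange[1L] * min(h, w), radiusRange[2L] * min(h, w),
               by = radiusStep)
  cand <- list()
  for (r in radii) {
    # vote along +/- gradient direction (rim gradients point inward for a
    # bright disk, but the sign depends on contrast polarity)
    cxv <- c(ex - r * ux, ex + r * ux)
    cyv <- c(ey - r * uy, ey + r * uy)
    ok <- cxv >= 0 & cxv <= w - 1 & cyv >= 0 & cyv <= h - 1
    if (!any(ok)) next
    idx <- round(cyv[ok]) + h * round(cxv[ok]) + 1L
    acc <- matrix(tabulate(idx, h * w), h, w)
    # 3x3 box smoothing absorbs rasterisation scatter
    accS <- matrix(0, h, w)
    for (dy in -1:1) for (dx in -1:1)
      accS <- accS + .shiftReplicate(acc, dy, dx)
    peak <- which.max(accS)
    if (accS[peak] < 6) next
    cand[[length(cand) + 1L]] <-
      c(x = (peak - 1L) %/% h, y = (peak - 1L) %% h, r = r)
  }
  if (!length(cand)) noFov("no circle candidate found")

  dl <- vapply(cand, function(ck) .deltaL(gray, ck["x"], ck["y"], ck["r"],
                                          deltaR), numeric(1))
  if (all(!is.finite(dl)) || max(dl, na.rm = TRUE) <= 0)
    noFov("no candidate circle shows a lightness change at its rim")
  best <- cand[[which.max(dl)]]

  # local refinement under the same Delta-L criterion
  bestDl <- -Inf; bestPar <- best
  for (dxc in -2:2) for (dyc in -2:2) for (drc in -2:2) {
    x0 <- best["x"] + dxc; y0 <- best["y"] + dyc; r0 <- best["r"] + drc
    if (r0 <= 2) next
    v <- .deltaL(gray, x0, y0, r0, deltaR)
    if (is.finite(v) && v > bestDl) {
      bestDl <- v
      bestPar <- c(x = unname(x0), y = unname(y0), r = unname(r0))
    }
  }
  new("FovCircle", x = unname(bestPar["x"]), y = unname(bestPar["y"]),
      r = unname(bestPar["r"]), deltaL = bestDl)
}

#' Detect the focus point
#'
#' Gaussian-smooths the luminance image at scale \code{sigmaSmooth}, applies
#' the Laplacian, and returns the coordinate of the maximum squared response
#' \eqn{S(x,y) = (\nabla^2 I_G)^2} -- the sharpest point of the frame. Ties
#' are broken by the smallest row, then the smallest column; a flat response
#' (constant image) returns (0, 0) with the flat flag set.
#'
#' @param gray luminance matrix in \[0,1\].
#' @param sigmaSmooth Gaussian scale (px) of the smoothing.
#' @return list with \code{x}, \code{y} (0-based column/row of the focus
#'   point), \code{value} (peak response) and \code{flat} (logical).
#' @seealso [focusScore()]
#' @export
detectFocusPoint <- function(gray, sigmaSmooth = 2) {
  .assertGray(gray)
  s <- .laplacian(.gaussBlurMat(gray, sigmaSmooth))^2
  mx <- max(s)
  if (mx < 1e-12)
    return(list(x = 0, y = 0, value = 0, flat = TRUE))
  hits <- which(s == mx, arr.ind = TRUE)
  # smallest row, then smallest column
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(x = unname(hits[1L, 2L]) - 1, y = unname(hits[1L, 1L]) - 1,
       value = mx, flat = FALSE)
}

#' Focus score
#'
#' How centrally the frame is focused: the FOV radius minus the Euclidean
#' distance of the focus point from the FOV centre,
#' \eqn{S_F = r_{FOV} - \|(x_f, y_f) - (x_{FOV}, y_{FOV})\|}, clamped below
#' at 0 so a focus point outside the FOV cannot go negative.
#'
#' @param fov a [FovCircle-class].
#' @param focusPoint numeric(2) (x, y) or the list returned by
#'   [detectFocusPoint()].
#' @return numeric(1), in px, in \[0, r_FOV\].
#' @export
focusScore <- function(fov, focusPoint) {
  stopifnot(is(fov, "FovCircle"))
  if (is.list(focusPoint)) focusPoint <- c(focusPoint$x, focusPoint$y)
  d <- sqrt((focusPoint[1L] - fov@x)^2 + (focusPoint[2L] - fov@y)^2)
  max(fov@r - d, 0)
}

#' Final blur score
#'
#' Product of the blur score and the focus score,
#' \eqn{S_{blf} = S_{bl} \times S_F}: a frame must be both sharp overall and
#' focused near the FOV centre to score high; either factor at zero
#' annihilates the product.
#'
#' @param sBl blur score (>= 0).
#' @param sF focus score (>= 0).
#' @return numeric(1).
#' @export
finalBlurScore <- function(sBl, sF) {
  stopifnot(is.finite(sBl), sBl >= 0, is.finite(sF), sF >= 0)
  sBl * sF
}

#' Full clarity assessment of one frame
#'
#' Composes the clarity stage: FOV detection, edge-energy sampling, mixture
#' fit, blur score (contrast = standard deviation of luminance inside the
#' FOV), focus point, focus score, and their product. A frame whose FOV
#' cannot be detected is returned with \code{noFov = TRUE} and
#' \code{sBlf = 0} rather than an error, so a video run never stops on a
#' degenerate frame.
#'
#' @param image RGB array or luminance matrix in \[0,1\].
#' @param sigmaSmooth Gaussian scale of the focus-point detector.
#' @param deltaR annulus width (px) of the FOV selector.
#' @param radiusRange FOV radius search range (fractions of min(H, W)).
#' @param eps blur-score denominator guard.
#' @param seed seed for the mixture initialisation.
#' @return a [ClarityResult-class].
#' @export
clarityScore <- function(image, sigmaSmooth = 2, deltaR = 5,
                         radiusRange = c(0.25, 0.60), eps = 1e-6,
                         seed = 1L) {
  gray <- toGrayscale(image)
  fov <- tryCatch(detectFov(gray, radiusRange = radiusRange, deltaR = deltaR),
                  otomifNoFov = function(e) NULL)
  if (is.null(fov)) {
    return(new("ClarityResult", sigmaMax = 0, contrast = 0, sBl = 0,
               focusX = NA_real_, focusY = NA_real_, flatFocus = FALSE,
               sF = 0, sBlf = 0, fov = NULL, noFov = TRUE))
  }
  sample <- edgeEnergy(gray, fov)
  fit <- fitEdgeGmm(sample, seed = seed)
  interior <- .circleMask(nrow(gray), ncol(gray), fov@x, fov@y, fov@r)
  contrast <- stats::sd(gray[interior])
  sBl <- blurScore(fit, contrast, eps = eps)
  fp <- detectFocusPoint(gray, sigmaSmooth = sigmaSmooth)
  sF <- focusScore(fov, fp)
  new("ClarityResult", sigmaMax = fit@sigmaMax, contrast = contrast,
      sBl = sBl, focusX = fp$x, focusY = fp$y, flatFocus = fp$flat,
      sF = sF, sBlf = finalBlurScore(sBl, sF), fov = fov, noFov = FALSE)
}
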