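# Synthetic otoscope-like frames with full ground truth: a bright textured
# field-of-view disk on a dark surround, an optional "eardrum" disk with a
# distinct colour/texture, controllable Gaussian blur inside the FOV, and an
# optional sharp high-contrast patch exempted from the blur (the focus
# point). Everything downstream (view classes, coverage masks, blur and
# focus scores, end-to-end selection) can be validated against these frames.

#' Construct a synthetic frame specification
#'
#' Convenience constructor for [FrameSpec-class]; validates geometry (the FOV
#' circle must fit inside the image; the eardrum disk must match the declared
#' visibility class).
#'
#' @param imageSize integer(2), (height, width) in pixels.
#' @param fovCenter numeric(2), (x, y) FOV centre, 0-based pixel coordinates.
#' @param fovRadius FOV radius in pixels.
#' @param eardrumCenter,eardrumRadius geometry of the eardrum disk (ignored
#'   for \code{visibility = "none"}).
#' @param visibility \code{"full"}, \code{"partial"} or \code{"none"}.
#' @param blurSigma Gaussian blur standard deviation (px) applied inside the
#'   FOV after composition; 0 disables blurring.
#' @param focusOffset numeric(2) (dx, dy) of the sharp patch relative to the
#'   FOV centre, or \code{NULL} for no sharp patch.
#' @param patchRadius radius (px) of the sharp patch.
#' @param textureSeed integer seed making the rendering deterministic.
#' @param noiseStd standard deviation of additive pixel noise.
#' @return a validated [FrameSpec-class].
#' @examples
#' sp <- frameSpec(c(160, 160), fovRadius = 60, visibility = "full")
#' sp
#' @export
frameSpec <- function(imageSize = c(160L, 160L),
                      fovCenter = (rev(imageSize) - 1) / 2,
                      fovRadius = 0.35 * min(imageSize),
                      eardrumCenter = fovCenter,
                      eardrumRadius = 0.5 * fovRadius,
                      visibility = c("full", "partial", "none"),
                      blurSigma = 0,
                      focusOffset = NULL,
                      patchRadius = 12,
                      textureSeed = 1L,
                      noiseStd = 0.02) {
  visibility <- match.arg(visibility)
  new("FrameSpec",
      imageSize = as.integer(imageSize),
      fovCenter = as.numeric(fovCenter),
      fovRadius = as.numeric(fovRadius),
      eardrumCenter = as.numeric(eardrumCenter),
      eardrumRadius = as.numeric(eardrumRadius),
      visibility = visibility,
      blurSigma = as.numeric(blurSigma),
      focusOffset = if (is.null(focusOffset)) numeric() else as.numeric(focusOffset),
      patchRadius = as.numeric(patchRadius),
      textureSeed = as.integer(textureSeed),
      noiseStd = as.numeric(noiseStd))
}

# Band-limited texture: smoothed uniform noise rescaled to a target sd.
.bandTexture <- function(h, w, smoothSigma, amplitude) {
  m <- .gaussBlurMat(matrix(stats::runif(h * w, -1, 1), h, w), smoothSigma)
  s <- stats::sd(as.vector(m))
  if (s < 1e-12) return(matrix(0, h, w))
  m * (amplitude / s)
}

#' Render a synthetic otoscope frame
#'
#' Renders the frame described by a [FrameSpec-class]: a dark surround (mean
#' intensity below 0.1), a bright reddish-textured FOV disk, a paler textured
#' eardrum disk clipped to the FOV when visibility is not \code{"none"}, an
#' optional high-contrast checker patch, additive Gaussian pixel noise, and
#' finally Gaussian blur applied inside the FOV but not within the sharp
#' patch. Rendering is bit-identical for identical specs.
#'
#' @param spec a [FrameSpec-class].
#' @return a [SyntheticFrame-class] with the image and ground-truth FOV and
#'   eardrum masks.
#' @examples
#' fr <- generateFrame(frameSpec(c(96, 96), fovRadius = 36,
#'                               visibility = "full", textureSeed = 7))
#' mean(fr@eardrumMask)
#' @export
generateFrame <- function(spec) {
  stopifnot(is(spec, "FrameSpec"))
  validObject(spec)
  h <- spec@imageSize[1L]; w <- spec@imageSize[2L]
  .withSeed(spec@textureSeed, {
    fovMask <- .circleMask(h, w, spec@fovCenter[1L], spec@fovCenter[2L],
                           spec@fovRadius)
    eardrumMask <- matrix(FALSE, h, w)
    if (spec@visibility != "none") {
      eardrumMask <- .circleMask(h, w, spec@eardrumCenter[1L],
                                 spec@eardrumCenter[2L], spec@eardrumRadius) &
        fovMask
    }

    img <- array(0, c(h, w, 3))
    # dark surround with faint texture
    surround <- 0.02 + 0.02 * (.bandTexture(h, w, 2, 1) * 0.5 + 0.5)
    for (c in 1:3) img[, , c] <- .clip01(surround)

    # bright reddish ear-canal texture inside the FOV
    # two texture bands (fine + coarse) give the canal a broadband spectrum,
    # so increasing Gaussian blur removes edge energy progressively rather
    # than all at once
    lum <- .bandTexture(h, w, 0.8, 0.07) + .bandTexture(h, w, 3, 0.06)
    colvar <- .bandTexture(h, w, 4, 0.04)
    base <- c(0.75, 0.47, 0.36)
    for (c in 1:3) {
      layer <- base[c] + lum + (c - 2) * colvar
      img[, , c][fovMask] <- layer[fovMask]
    }

    # pale canal-wall highlights: soft elliptical patches whose colour is
    # close to the eardrum's, drawn before (hence behind) the eardrum disk.
    # They give the background the eardrum-like structures (skin folds,
    # reflections) that make foreground-only activation maps over-activate,
    # the regime the background-subtraction refinement addresses.
    nBlob <- sample(2:4, 1L)
    blobColor <- c(0.88, 0.80, 0.64)
    for (b in seq_len(nBlob)) {
      br <- stats::runif(1, 0.10, 0.22) * spec@fovRadius
      ba <- stats::runif(1, 0, 2 * pi)
      bd <- stats::runif(1, 0.45, 0.95) * spec@fovRadius
      bx <- spec@fovCenter[1L] + bd * cos(ba)
      by <- spec@fovCenter[2L] + bd * sin(ba)
      alpha <- exp(-.dist2Grid(h, w, bx, by) / (2 * br^2)) * 0.85
      alpha[!fovMask] <- 0
      for (c in 1:3)
        img[, , c] <- (1 - alpha) * img[, , c] + alpha * blobColor[c]
    }

    # frames without an eardrum look down the canal: a dark elliptical
    # recess (the canal lumen) gives the eardrum-absent class positive
    # image evidence of its own
    if (spec@visibility == "none") {
      hd <- stats::runif(1, 0.25, 0.45) * spec@fovRadius
      ha <- stats::runif(1, 0, 2 * pi)
      hdd <- stats::runif(1, 0, 0.45) * spec@fovRadius
      hx <- spec@fovCenter[1L] + hdd * cos(ha)
      hy <- spec@fovCenter[2L] + hdd * sin(ha)
      holeC <- c(0.22, 0.10, 0.08)
      alpha <- exp(-.dist2Grid(h, w, hx, hy) / (2 * hd^2)) * 0.9
      alpha[!fovMask] <- 0
      for (c in 1:3)
        img[, , c] <- (1 - alpha) * img[, , c] + alpha * holeC[c]
    }

    # eardrum disk: a pale discriminative core fading to a semi-transparent
    # periphery whose colour approaches the canal (real membranes are
    # translucent at the rim), plus a bright elliptical light reflex below
    # the centre -- image-level evidence is deliberately non-uniform across
    # the membrane, as it is in real otoscopy
    if (any(eardrumMask)) {
      elum <- .bandTexture(h, w, 1, 0.05)
      rel <- sqrt(.dist2Grid(h, w, spec@eardrumCenter[1L],
                             spec@eardrumCenter[2L])) / spec@eardrumRadius
      # periphery keeps a weak pale tint: rim evidence is weak but nonzero
      mix <- 0.7 * pmin(pmax((rel - 0.35) / 0.65, 0), 1)  # 0 core -> 0.7 rim
      core <- c(0.88, 0.82, 0.68); rim <- c(0.77, 0.54, 0.44)
      for (c in 1:3) {
        val <- (1 - mix) * core[c] + mix * rim[c] + elum
        layer <- img[, , c]
        layer[eardrumMask] <- val[eardrumMask]
        img[, , c] <- layer
      }
      refC <- c(0.97, 0.95, 0.86)
      ref <- exp(-.dist2Grid(h, w, spec@eardrumCenter[1L],
                             spec@eardrumCenter[2L] + 0.35 * spec@eardrumRadius) /
                 (2 * (0.28 * spec@eardrumRadius)^2))
      ref[!eardrumMask] <- 0
      for (c in 1:3)
        img[, , c] <- (1 - ref) * img[, , c] + ref * refC[c]
    }

    # sharp high-contrast checker patch at the focus point
    patchMask <- matrix(FALSE, h, w)
    if (length(spec@focusOffset) == 2L) {
      px <- spec@fovCenter[1L] + spec@focusOffset[1L]
      py <- spec@fovCenter[2L] + spec@focusOffset[2L]
      patchMask <- .circleMask(h, w, px, py, spec@patchRadius)
      checker <- outer(seq_len(h) - 1L, seq_len(w) - 1L,
                       function(y, x) (((x %/% 4L) + (y %/% 4L)) %% 2L) == 0L)
      for (c in 1:3) {
        layer <- img[, , c]
        layer[patchMask & checker] <- 0.95
        layer[patchMask & !checker] <- 0.15
        img[, , c] <- layer
      }
    }

    if (spec@noiseStd > 0)
      img <- img + array(stats::rnorm(h * w * 3, 0, spec@noiseStd), c(h, w, 3))
    img <- .clip01(img)

    if (spec@blurSigma > 0) {
      blurred <- .gaussBlurImg(img, spec@blurSigma)
      keepSharp <- !fovMask | patchMask
      for (c in 1:3) {
        layer <- blurred[, , c]
        layer[keepSharp] <- img[, , c][keepSharp]
        img[, , c] <- layer
      }
    }

    new("SyntheticFrame", image = img, spec = spec,
        eardrumMask = eardrumMask, fovMask = fovMask)
  })
}

# Distance between circle centres at which `outsideFrac` of the small
# circle's area falls outside the big one (bisection on the overlap area).
.partialOffsetDistance <- function(fovRadius, eardrumRadius, outsideFrac) {
  target <- (1 - outsideFrac) * pi * eardrumRadius^2
  lo <- max(fovRadius - eardrumRadius, 0); hi <- fovRadius + eardrumRadius
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.circleOverlapArea(fovRadius, eardrumRadius, mid) > target) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Draw a random valid frame specification
#'
#' Samples a [FrameSpec-class] of the requested visibility class with
#' plausible geometry: FOV radius 28--40% of the short image side, eardrum
#' radius 35--60% of the FOV radius; \code{"partial"} frames place the disk
#' so that 25--75% of its area falls outside the FOV.
#'
#' @param seed integer seed; the spec is a deterministic function of it.
#' @param imageSize integer(2) (height, width).
#' @param visibility visibility class of the sampled frame.
#' @param blurSigma blur level passed through to the spec.
#' @param focus \code{"none"} (no sharp patch), \code{"center"} (patch at the
#'   FOV centre) or \code{"random"} (patch uniformly inside 0.7 of the FOV
#'   radius).
#' @param noiseStd additive noise level.
#' @return a [FrameSpec-class].
#' @export
randomFrameSpec <- function(seed, imageSize = c(160L, 160L),
                            visibility = c("full", "partial", "none"),
                            blurSigma = 0,
                            focus = c("none", "center", "random"),
                            noiseStd = 0.02) {
  visibility <- match.arg(visibility)
  focus <- match.arg(focus)
  h <- imageSize[1L]; w <- imageSize[2L]
  .withSeed(seed, {
    r <- stats::runif(1, 0.28, 0.40) * min(h, w)
    cx <- stats::runif(1, r + 1, (w - 1) - r - 1)
    cy <- stats::runif(1, r + 1, (h - 1) - r - 1)
    er <- stats::runif(1, 0.35, 0.60) * r
    if (visibility == "full") {
      d <- stats::runif(1, 0, max(r - er - 1, 0))
    } else if (visibility == "partial") {
      d <- .partialOffsetDistance(r, er, stats::runif(1, 0.25, 0.75))
    } else d <- 0
    ang <- stats::runif(1, 0, 2 * pi)
    ec <- c(cx + d * cos(ang), cy + d * sin(ang))
    off <- switch(focus,
      none = NULL,
      center = c(0, 0),
      random = {
        rr <- stats::runif(1, 0, 0.7 * r); aa <- stats::runif(1, 0, 2 * pi)
        c(rr * cos(aa), rr * sin(aa))
      })
    frameSpec(imageSize = imageSize, fovCenter = c(cx, cy), fovRadius = r,
              eardrumCenter = ec, eardrumRadius = er,
              visibility = visibility, blurSigma = blurSigma,
              focusOffset = off, textureSeed = seed, noiseStd = noiseStd)
  })
}

#' Generate a labelled shapes dataset for classifier training
#'
#' Builds a class-balanced set of synthetic frames with image-level labels
#' and ground-truth eardrum masks, the training surrogate for classifiers
#' learned from image-level labels only.
#'
#' With \code{classes = "binary"} (default) labels are
#' \code{absent}/\code{present} (present mixes full and partial views), the
#' setup of the background/eardrum head behind the coverage stage. With
#' \code{classes = "view"} labels are \code{none}/\code{partial}/\code{full},
#' the 3-class eardrum-view head. Balance is within one image per class;
#' a fixed seed reproduces the dataset exactly.
#'
#' @param n number of images (at least 2).
#' @param seed integer seed.
#' @param classes \code{"binary"} or \code{"view"}.
#' @param imageSize integer(2) (height, width) of the rendered frames.
#' @return an [ImageDataset-class].
#' @examples
#' ds <- generateShapesDataset(10, seed = 1)
#' table(classLabels(ds))
#' @export
generateShapesDataset <- function(n, seed, classes = c("binary", "view"),
                                  imageSize = c(64L, 64L)) {
  classes <- match.arg(classes)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  labs <- if (classes == "binary") c("absent", "present") else
    c("none", "partial", "full")
  labelSeq <- rep_len(labs, n)
  images <- masks <- specs <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labelSeq[i]
    vis <- switch(lab,
      absent = "none", none = "none", partial = "partial",
      present = if (i %% 4L == 0L) "partial" else "full",
      full = "full")
    sp <- randomFrameSpec(as.integer((as.double(seed) * 100003) %% 2147480000) + i,
                          imageSize = imageSize, visibility = vis)
    fr <- generateFrame(sp)
    images[[i]] <- fr@image
    masks[[i]] <- fr@eardrumMask
    specs[[i]] <- sp
  }
  new("ImageDataset", images = images,
      labels = factor(labelSeq, levels = labs),
      masks = masks, specs = specs)
}

#' Design a video with one clearly best frame
#'
#' Returns specifications for an \code{n}-frame synthetic video in which
#' exactly one frame is designed to win on all three scoring axes: full
#' eardrum visibility with high coverage, zero blur, and a sharp patch at the
#' FOV centre. The remaining frames are degraded (blurred, partial or absent
#' eardrum, off-centre or missing focus).
#'
#' @param seed integer seed.
#' @param n number of frames (at least 2).
#' @param imageSize integer(2) (height, width).
#' @return list with \code{specs} (list of [FrameSpec-class]) and
#'   \code{bestIndex} (0-based frame index of the designed best frame).
#' @export
designBestFrameVideo <- function(seed, n = 10L, imageSize = c(160L, 160L)) {
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  .withSeed(seed, {
    bestPos <- sample.int(n, 1L)
    specs <- vector("list", n)
    degrade <- c("blur", "partial", "none", "offfocus")
    for (i in seq_len(n)) {
      s <- as.integer((as.double(seed) * 7919) %% 2147480000) + i
      if (i == bestPos) {
        specs[[i]] <- .withSeed(s, {
          h <- imageSize[1L]; w <- imageSize[2L]
          r <- 0.38 * min(h, w)
          frameSpec(imageSize = imageSize,
                    fovCenter = c((w - 1) / 2, (h - 1) / 2), fovRadius = r,
                    eardrumCenter = c((w - 1) / 2, (h - 1) / 2),
                    eardrumRadius = 0.65 * r,
                    visibility = "full", blurSigma = 0,
                    focusOffset = c(0, 0), textureSeed = s)
        })
      } else {
        kind <- degrade[1L + (i %% length(degrade))]
        specs[[i]] <- switch(kind,
          blur = randomFrameSpec(s, imageSize, visibility = "full",
                                 blurSigma = stats::runif(1, 3, 6),
                                 focus = "none"),
          partial = randomFrameSpec(s, imageSize, visibility = "partial",
                                    blurSigma = stats::runif(1, 1.5, 3),
                                    focus = "none"),
          none = randomFrameSpec(s, imageSize, visibility = "none",
                                 blurSigma = stats::runif(1, 1.5, 4),
                                 focus = "none"),
          offfocus = randomFrameSpec(s, imageSize, visibility = "partial",
                                     blurSigma = stats::runif(1, 2, 4),
                                     focus = "random"))
      }
    }
    list(specs = specs, bestIndex = bestPos - 1L)
  })
}

#' Write a synthetic video and its ground-truth sidecar
#'
#' Renders each spec and writes the frames either as a multi-page TIFF (a
#' lossless container, 8-bit) or as a directory of numbered PNG frames, plus
#' a CSV sidecar with per-frame ground truth: visibility class, eardrum
#' coverage fraction, blur sigma, focus location (NA when the frame has no
#' sharp patch), FOV geometry and, when \code{bestIndex} is given, a
#' \code{designed_best} flag.
#'
#' Frames are quantised to 8 bits before writing (as any video codec would);
#' decoding with [readFrames()] recovers the written pixels exactly.
#'
#' @param specs list of [FrameSpec-class], all with the same image size.
#' @param path output path: a \code{.tif}/\code{.tiff} file or a directory
#'   (created) for PNG frames.
#' @param format \code{"tiff"} or \code{"png"}; default follows the path
#'   extension.
#' @param bestIndex optional 0-based index of a designed best frame, flagged
#'   in the sidecar.
#' @return invisibly, a list with \code{path}, \code{sidecar} (CSV path) and
#'   \code{truth} (the sidecar data.frame).
#' @export
generateVideo <- function(specs, path, format = NULL, bestIndex = NULL) {
  stopifnot(length(specs) >= 1L)
  sizes <- vapply(specs, function(s) paste(s@imageSize, collapse = "x"),
                  character(1))
  if (length(unique(sizes)) != 1L)
    stop("all specs must share the same image size", call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "png"
  format <- match.arg(format, c("tiff", "png"))

  frames <- lapply(specs, generateFrame)
  quantised <- lapply(frames, function(fr) round(fr@image * 255) / 255)

  truth <- data.frame(
    frame_index = seq_along(specs) - 1L,
    visibility = vapply(specs, function(s) s@visibility, character(1)),
    coverage = vapply(frames, function(fr) mean(fr@eardrumMask), numeric(1)),
    blur_sigma = vapply(specs, function(s) s@blurSigma, numeric(1)),
    focus_x = vapply(specs, function(s)
      if (length(s@focusOffset)) s@fovCenter[1L] + s@focusOffset[1L] else NA_real_,
      numeric(1)),
    focus_y = vapply(specs, function(s)
      if (length(s@focusOffset)) s@fovCenter[2L] + s@focusOffset[2L] else NA_real_,
      numeric(1)),
    fov_x = vapply(specs, function(s) s@fovCenter[1L], numeric(1)),
    fov_y = vapply(specs, function(s) s@fovCenter[2L], numeric(1)),
    fov_r = vapply(specs, function(s) s@fovRadius, numeric(1))
  )
  if (!is.null(bestIndex))
    truth$designed_best <- truth$frame_index == bestIndex

  if (format == "tiff") {
    ok <- dir.exists(dirname(path)) || dir.create(dirname(path), recursive = TRUE)
    if (!ok) stop("cannot create directory for ", path, call. = FALSE)
    wrote <- try(tiff::writeTIFF(quantised, path, bits.per.sample = 8L,
                                 compression = "LZW"), silent = TRUE)
    if (inherits(wrote, "try-error"))
      stop("unwritable path: ", path, call. = FALSE)
    sidecar <- sub("\\.tiff?$", ".csv", path, ignore.case = TRUE)
  } else {
    ok <- dir.exists(path) || dir.create(path, recursive = TRUE)
    if (!ok) stop("unwritable path: ", path, call. = FALSE)
    for (i in seq_along(quantised))
      png::writePNG(quantised[[i]],
                    file.path(path, sprintf("frame_%04d.png", i - 1L)))
    sidecar <- file.path(path, "sidecar.csv")
  }
  utils::write.csv(truth, sidecar, row.names = FALSE)
  invisible(list(path = path, sidecar = sidecar, truth = truth))
}
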