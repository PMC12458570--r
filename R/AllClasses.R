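#' @import methods
NULL

setClassUnion("FovCircleOrNULL", "NULL")

#' Configuration for adversarial climbing
#'
#' Holds the knobs of the iterative adversarial-climbing refinement of class
#' activation maps: the ascent step size, the number of iterations, the weight
#' of the regularisation that restricts growth of already highly activated
#' regions, the relative threshold used both for that high-activation mask and
#' for binarising final maps, and the weight of the background map subtracted
#' in the binary-class refinement.
#'
#' @slot eps numeric(1), ascent step size per iteration in input-intensity
#'   units (images live in \[0,1\]).
#' @slot iterations integer(1), number of climbing iterations (0 reduces the
#'   method to plain Grad-CAM).
#' @slot lambdaRestrict numeric(1), weight of the regularisation term that
#'   penalises changes of the activation map inside already-activated regions.
#' @slot maskThreshold numeric(1) in (0,1), fraction of the map maximum above
#'   which a pixel counts as highly activated.
#' @slot bcLambda numeric(1), weight on the background activation map
#'   subtracted from the foreground map in the binary-class refinement.
#' @seealso [climbingConfig()], [adversarialClimb()], [bcAdvCAM()]
#' @export
setClass("ClimbingConfig",
  representation(
    eps = "numeric",
    iterations = "integer",
    lambdaRestrict = "numeric",
    maskThreshold = "numeric",
    bcLambda = "numeric"
  )
)

setValidity("ClimbingConfig", function(object) {
  msg <- character()
  if (length(object@eps) != 1L || !is.finite(object@eps) || object@eps <= 0)
    msg <- c(msg, "'eps' must be a single positive number")
  if (length(object@iterations) != 1L || is.na(object@iterations) ||
      object@iterations < 0L)
    msg <- c(msg, "'iterations' must be a single non-negative integer")
  if (length(object@maskThreshold) != 1L || !is.finite(object@maskThreshold) ||
      object@maskThreshold <= 0 || object@maskThreshold >= 1)
    msg <- c(msg, "'maskThreshold' must lie strictly between 0 and 1")
  if (length(object@lambdaRestrict) != 1L || !is.finite(object@lambdaRestrict) ||
      object@lambdaRestrict < 0)
    msg <- c(msg, "'lambdaRestrict' must be a single non-negative number")
  if (length(object@bcLambda) != 1L || !is.finite(object@bcLambda) ||
      object@bcLambda < 0)
    msg <- c(msg, "'bcLambda' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Specification of one synthetic otoscope frame
#'
#' Describes the geometry and degradations of a synthetic otoscope-like frame:
#' a bright circular field of view (FOV) on a dark surround, an optional
#' textured "eardrum" disk inside it, Gaussian blur, and an optional sharp
#' patch exempted from the blur that acts as the frame's focus point.
#'
#' Coordinates are 0-based \code{(x, y) = (column, row)} with the origin at
#' the top-left pixel, the convention used throughout the package.
#'
#' @slot imageSize integer(2), (height, width) in pixels.
#' @slot fovCenter numeric(2), (x, y) centre of the FOV circle.
#' @slot fovRadius numeric(1), FOV radius in pixels; the circle must fit
#'   inside the image.
#' @slot eardrumCenter numeric(2), (x, y) centre of the eardrum disk.
#' @slot eardrumRadius numeric(1), eardrum disk radius in pixels.
#' @slot visibility character(1), one of \code{"full"}, \code{"partial"},
#'   \code{"none"}. \code{full} requires the disk entirely inside the FOV,
#'   \code{partial} requires it clipped by the FOV boundary, \code{none} draws
#'   no disk.
#' @slot blurSigma numeric(1), standard deviation (px) of the Gaussian blur
#'   applied inside the FOV after composition.
#' @slot focusOffset numeric, either length 0 (no sharp patch) or (dx, dy)
#'   offset of the sharp patch centre relative to the FOV centre.
#' @slot patchRadius numeric(1), radius (px) of the sharp patch.
#' @slot textureSeed integer(1), seed for all stochastic texture; identical
#'   specs render bit-identical frames.
#' @slot noiseStd numeric(1), standard deviation of additive pixel noise in
#'   \[0,1\] intensity units.
#' @seealso [frameSpec()], [generateFrame()]
#' @export
setClass("FrameSpec",
  representation(
    imageSize = "integer",
    fovCenter = "numeric",
    fovRadius = "numeric",
    eardrumCenter = "numeric",
    eardrumRadius = "numeric",
    visibility = "character",
    blurSigma = "numeric",
    focusOffset = "numeric",
    patchRadius = "numeric",
    textureSeed = "integer",
    noiseStd = "numeric"
  )
)

setValidity("FrameSpec", function(object) {
  msg <- character()
  h <- object@imageSize[1L]; w <- object@imageSize[2L]
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "'imageSize' must be (height, width), each >= 16 px")
  if (!object@visibility %in% c("full", "partial", "none"))
    msg <- c(msg, "'visibility' must be one of 'full', 'partial', 'none'")
  r <- object@fovRadius
  cx <- object@fovCenter[1L]; cy <- object@fovCenter[2L]
  if (!is.finite(r) || r <= 0)
    msg <- c(msg, "'fovRadius' must be positive")
  else if (cx - r < 0 || cy - r < 0 || cx + r > w - 1 || cy + r > h - 1)
    msg <- c(msg, sprintf(
      "FOV circle (centre (%g, %g), radius %g) does not fit inside the %d x %d image",
      cx, cy, r, h, w))
  if (object@blurSigma < 0) msg <- c(msg, "'blurSigma' must be >= 0")
  if (object@noiseStd < 0) msg <- c(msg, "'noiseStd' must be >= 0")
  if (!length(object@focusOffset) %in% c(0L, 2L))
    msg <- c(msg, "'focusOffset' must be empty or length 2 (dx, dy)")
  if (object@visibility != "none") {
    er <- object@eardrumRadius
    if (!is.finite(er) || er <= 0)
      msg <- c(msg, "'eardrumRadius' must be positive when the eardrum is drawn")
    d <- sqrt(sum((object@eardrumCenter - object@fovCenter)^2))
    if (object@visibility == "full" && is.finite(er) && d + er > r + 1e-9)
      msg <- c(msg, "visibility 'full' requires the eardrum disk entirely inside the FOV")
    if (object@visibility == "partial" && is.finite(er) &&
        (d + er <= r + 1e-9 || d - er >= r - 1e-9))
      msg <- c(msg, "visibility 'partial' requires the eardrum disk to be clipped by the FOV boundary")
  }
  if (length(msg)) msg else TRUE
})

#' A rendered synthetic frame with ground truth
#'
#' @slot image numeric array height x width x 3, RGB in \[0,1\].
#' @slot spec the [FrameSpec-class] the frame was rendered from.
#' @slot eardrumMask logical matrix, ground-truth eardrum segmentation
#'   (always a subset of \code{fovMask}).
#' @slot fovMask logical matrix, ground-truth field-of-view disk.
#' @seealso [generateFrame()]
#' @export
setClass("SyntheticFrame",
  representation(
    image = "array",
    spec = "FrameSpec",
    eardrumMask = "matrix",
    fovMask = "matrix"
  )
)

setValidity("SyntheticFrame", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3L] != 3L)
    return("'image' must be a height x width x 3 array")
  if (!identical(dim(object@eardrumMask), d[1:2]) ||
      !identical(dim(object@fovMask), d[1:2]))
    return("masks must have the same height/width as the image")
  if (any(object@eardrumMask & !object@fovMask))
    return("'eardrumMask' must be a subset of 'fovMask'")
  TRUE
})

#' A labelled set of synthetic images
#'
#' Container for generator output used to train and evaluate classifiers:
#' images, image-level labels, and (where applicable) ground-truth masks.
#'
#' @slot images list of height x width x 3 arrays in \[0,1\].
#' @slot labels factor of image-level class labels, one per image.
#' @slot masks list of logical matrices (ground-truth eardrum masks; an
#'   all-FALSE matrix for images without an eardrum).
#' @slot specs list of [FrameSpec-class] objects the images were rendered from.
#' @export
setClass("ImageDataset",
  representation(
    images = "list",
    labels = "factor",
    masks = "list",
    specs = "list"
  )
)

setValidity("ImageDataset", function(object) {
  n <- length(object@images)
  if (length(object@labels) != n || length(object@masks) != n)
    return("'images', 'labels' and 'masks' must have equal length")
  TRUE
})

#' A sequence of decoded video frames
#'
#' @slot frames list of height x width x 3 numeric arrays in \[0,1\].
#' @slot frameIndex integer vector of original frame indices (0-based),
#'   unique and increasing.
#' @slot timestamp numeric vector of per-frame timestamps in seconds
#'   (\code{NA} when the container carries none).
#' @slot source character(1), path the frames were decoded from.
#' @seealso [readFrames()]
#' @export
setClass("OtoFrames",
  representation(
    frames = "list",
    frameIndex = "integer",
    timestamp = "numeric",
    source = "character"
  )
)

setValidity("OtoFrames", function(object) {
  n <- length(object@frames)
  if (length(object@frameIndex) != n || length(object@timestamp) != n)
    return("'frameIndex' and 'timestamp' must have one entry per frame")
  if (anyDuplicated(object@frameIndex))
    return("'frameIndex' must be unique within one video")
  TRUE
})

#' Compact convolutional image classifier
#'
#' A small CNN (two 3x3 convolution blocks, global average pooling, linear
#' head) with forward and backward passes implemented in the package. It
#' exposes class logits, class probabilities, its last convolutional feature
#' maps, and gradients of arbitrary logit functionals with respect to both
#' the feature maps and the input image -- the plumbing required by Grad-CAM
#' and adversarial climbing.
#'
#' @slot params list of weight matrices/vectors (conv1, conv2, dense).
#' @slot classes character vector of class labels in logit order.
#' @slot inputSize integer(1), side length images are resized to.
#' @slot channelMean,channelSd numeric(3), per-channel normalisation
#'   statistics computed on the training set.
#' @slot config list of training hyper-parameters actually used.
#' @slot history list with per-epoch training/validation accuracy.
#' @seealso [trainViewClassifier()], [predictView()], [gradCAM()]
#' @export
setClass("ConvNetClassifier",
  representation(
    params = "list",
    classes = "character",
    inputSize = "integer",
    channelMean = "numeric",
    channelSd = "numeric",
    config = "list",
    history = "list"
  )
)

#' Class activation map on the image grid
#'
#' @slot values numeric matrix aligned to the source image grid, non-negative,
#'   min-max normalised to \[0,1\] by the producing operation.
#' @slot classId integer(1), index (1-based) of the class the map explains.
#' @seealso [gradCAM()], [adversarialClimb()], [bcAdvCAM()], [thresholdMask()]
#' @export
setClass("ActivationMap",
  representation(values = "matrix", classId = "integer")
)

setValidity("ActivationMap", function(object) {
  if (any(!is.finite(object@values)))
    return("'values' must be finite")
  if (any(object@values < 0))
    return("'values' must be non-negative")
  TRUE
})

#' Detected otoscope field-of-view circle
#'
#' @slot x,y numeric(1), circle centre in 0-based (column, row) pixel
#'   coordinates.
#' @slot r numeric(1), radius in pixels.
#' @slot deltaL numeric(1), the lightness change between the circle interior
#'   and its exterior annulus that selected this candidate.
#' @seealso [detectFov()], [focusScore()]
#' @export
setClass("FovCircle",
  representation(x = "numeric", y = "numeric", r = "numeric", deltaL = "numeric")
)

setValidity("FovCircle", function(object) {
  if (object@r <= 0) return("'r' must be positive")
  TRUE
})

setIs("FovCircle", "FovCircleOrNULL")

#' Two-component Gaussian mixture fitted to edge energies
#'
#' @slot means,sds,weights numeric(2), component parameters; weights sum to 1.
#' @slot sigmaMax numeric(1), standard deviation of the wider component --
#'   the spread statistic of the blur score.
#' @slot degenerate logical(1), TRUE when the sample was constant (or the fit
#'   collapsed) and \code{sigmaMax} is not a meaningful spread estimate.
#' @slot loglik numeric(1), final observed-data log-likelihood.
#' @slot iterations integer(1), EM iterations run.
#' @seealso [fitEdgeGmm()], [blurScore()]
#' @export
setClass("GmmFit",
  representation(
    means = "numeric", sds = "numeric", weights = "numeric",
    sigmaMax = "numeric", degenerate = "logical",
    loglik = "numeric", iterations = "integer"
  )
)

setValidity("GmmFit", function(object) {
  if (length(object@weights) == 2L &&
      abs(sum(object@weights) - 1) > 1e-6)
    return("'weights' must sum to 1")
  if (length(object@sds) == 2L && length(object@sigmaMax) == 1L &&
      abs(object@sigmaMax - max(object@sds)) > 1e-12)
    return("'sigmaMax' must equal the larger component standard deviation")
  TRUE
})

#' Per-frame clarity assessment
#'
#' Bundles everything the clarity stage computes for one frame: the detected
#' field of view, the edge-energy spread and contrast behind the blur score,
#' the focus point and focus score, and their product, the final blur score.
#'
#' @slot sigmaMax numeric(1), wider-component standard deviation of the
#'   edge-energy mixture.
#' @slot contrast numeric(1), RMS contrast (standard deviation of grayscale
#'   intensity) inside the FOV.
#' @slot sBl numeric(1), blur score \code{sigmaMax / (contrast + eps)};
#'   larger means clearer.
#' @slot focusX,focusY numeric(1), focus point, 0-based (column, row).
#' @slot flatFocus logical(1), TRUE when the sharpness response was flat and
#'   the focus point is the tie-break coordinate (0, 0).
#' @slot sF numeric(1), focus score: FOV radius minus distance of the focus
#'   point from the FOV centre, clamped below at 0 (px).
#' @slot sBlf numeric(1), final blur score, \code{sBl * sF}.
#' @slot fov the detected [FovCircle-class], or NULL when no FOV was found.
#' @slot noFov logical(1), TRUE when FOV detection failed (then
#'   \code{sBlf = 0}).
#' @seealso [clarityScore()]
#' @export
setClass("ClarityResult",
  representation(
    sigmaMax = "numeric", contrast = "numeric", sBl = "numeric",
    focusX = "numeric", focusY = "numeric", flatFocus = "logical",
    sF = "numeric", sBlf = "numeric",
    fov = "FovCircleOrNULL", noFov = "logical"
  )
)

#' End-to-end pipeline configuration
#'
#' @slot stride integer(1), keep frames whose index is 0 modulo stride.
#' @slot topK integer(1), number of frames to select.
#' @slot weights named numeric(3), rank-fusion weights for
#'   (view, coverage, blur); must be non-negative and sum to 1.
#' @slot cam a [ClimbingConfig-class] for the coverage stage.
#' @slot clarity list of clarity-stage settings: \code{sigmaSmooth} (px,
#'   Gaussian scale of the sharpness map), \code{deltaR} (px, exterior annulus
#'   width), \code{radiusRange} (fractions of min(H, W) searched for the FOV
#'   radius), \code{eps} (blur-score denominator guard).
#' @slot seed integer(1), seed for every stochastic step (GMM initialisation).
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
  representation(
    stride = "integer",
    topK = "integer",
    weights = "numeric",
    cam = "ClimbingConfig",
    clarity = "list",
    seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@stride < 1L) msg <- c(msg, "'stride' must be >= 1")
  if (object@topK < 1L) msg <- c(msg, "'topK' must be >= 1")
  w <- object@weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "'weights' must be 3 non-negative values summing to 1")
  if (length(msg)) msg else TRUE
})
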