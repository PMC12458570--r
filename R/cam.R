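# Weakly supervised eardrum localisation: Grad-CAM on the compact CNN,
# iterative adversarial climbing that expands the map beyond the most
# discriminative region, and the binary-class refinement that subtracts a
# weighted background map. Maps are binarised by a relative threshold and
# reduced to the coverage score.

#' Configuration constructor for adversarial climbing
#'
#' Defaults: 30 iterations, step size 0.008 on \[0,1\]-scaled input,
#' restriction weight 7, relative mask threshold 0.5, background-subtraction
#' weight 1.
#'
#' @param eps ascent step size per iteration.
#' @param iterations number of climbing iterations (0 = plain Grad-CAM).
#' @param lambdaRestrict weight of the regularisation restricting growth in
#'   already highly activated regions.
#' @param maskThreshold fraction of the map maximum defining "highly
#'   activated", also the default binarisation threshold.
#' @param bcLambda weight on the background map in the binary-class
#'   refinement.
#' @return a [ClimbingConfig-class].
#' @export
climbingConfig <- function(eps = 0.008, iterations = 30L, lambdaRestrict = 7,
                           maskThreshold = 0.5, bcLambda = 1) {
  new("ClimbingConfig", eps = as.numeric(eps),
      iterations = as.integer(iterations),
      lambdaRestrict = as.numeric(lambdaRestrict),
      maskThreshold = as.numeric(maskThreshold),
      bcLambda = as.numeric(bcLambda))
}

.resolveClassId <- function(classifier, classId) {
  if (is.character(classId)) {
    idx <- match(classId, classifier@classes)
    if (is.na(idx)) stop("unknown class '", classId, "'; classes are: ",
                         paste(classifier@classes, collapse = ", "),
                         call. = FALSE)
    return(idx)
  }
  idx <- as.integer(classId)
  if (is.na(idx) || idx < 1L || idx > length(classifier@classes))
    stop("'classId' out of range 1..", length(classifier@classes),
         call. = FALSE)
  idx
}

.normalize01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo < 1e-12) return(m * 0)
  (m - lo) / (hi - lo)
}

# Raw (unnormalised) Grad-CAM at feature resolution: ReLU of the
# gradient-weighted feature combination. With the GAP + linear head the
# per-pixel gradient of the class logit w.r.t. feature k is Wd[k, c] / n2,
# so the channel weights are exact, not estimated.
.rawCam <- function(params, cache, classIdx) {
  alpha <- params$Wd[, classIdx] / (cache$h2 * cache$w2)
  s <- drop(cache$A2 %*% alpha)
  matrix(pmax(s, 0), cache$h2, cache$w2)
}

.finalizeCam <- function(rawMat, h, w, classIdx) {
  up <- .resizeBilinearMat(rawMat, h, w)
  new("ActivationMap", values = .normalize01(pmax(up, 0)),
      classId = as.integer(classIdx))
}

#' Grad-CAM activation map
#'
#' Gradient-weighted class activation map of the classifier for one class:
#' the ReLU of the gradient-weighted combination of the last convolutional
#' feature maps, bilinearly upsampled to the image grid and min-max
#' normalised to \[0,1\].
#'
#' @param classifier a trained [ConvNetClassifier-class].
#' @param image a height x width x 3 RGB array in \[0,1\].
#' @param classId target class, as 1-based index or class name.
#' @return an [ActivationMap-class] aligned to the image grid.
#' @seealso [adversarialClimb()], [bcAdvCAM()], [thresholdMask()]
#' @export
gradCAM <- function(classifier, image, classId) {
  stopifnot(is(classifier, "ConvNetClassifier"))
  idx <- .resolveClassId(classifier, classId)
  X <- .preprocess(classifier, image)
  cache <- .nnForward(classifier@params, X)
  d <- dim(image)
  .finalizeCam(.rawCam(classifier@params, cache, idx), d[1L], d[2L], idx)
}

# One climbing trajectory at preprocessed resolution. Returns the summed
# raw CAM over the trajectory (including the starting point) plus the
# start/end logits of the target class. `channelSd` maps the step size,
# which is stated in [0,1] image-intensity units, into the standardised
# input space the network operates on.
.climbTrajectory <- function(params, X0, classIdx, config,
                             channelSd = c(1, 1, 1)) {
  nClasses <- length(params$bd)
  dlogits <- rep(-1, nClasses); dlogits[classIdx] <- 1
  cache <- .nnForward(params, X0)
  cam0 <- .rawCam(params, cache, classIdx)
  camSum <- cam0
  logit0 <- cache$logits[classIdx]
  X <- X0
  alpha <- params$Wd[, classIdx] / (cache$h2 * cache$w2)
  tIter <- config@iterations
  if (tIter > 0L) {
    for (t in seq_len(tIter)) {
      camCur <- .rawCam(params, cache, classIdx)
      # restriction: penalise |M * (CAM(x_t) - CAM(x_0))|_1 inside the
      # highly activated region of the current map
      camMax <- max(camCur)
      M <- if (camMax > 0) camCur > config@maskThreshold * camMax
           else matrix(FALSE, cache$h2, cache$w2)
      dCam <- -config@lambdaRestrict * as.numeric(M) * sign(camCur - cam0)
      reluMask <- as.numeric(camCur > 0)
      dA2extra <- outer(as.vector(dCam * reluMask), alpha)
      g <- .nnBackward(params, cache, dlogits, wrtInput = TRUE,
                       dA2extra = dA2extra, weightGrads = FALSE)
      if (any(!is.finite(g$dX)))
        stop("non-finite gradient during adversarial climbing ",
             "(degenerate classifier)", call. = FALSE)
      # the gradient is scaled to unit max-abs so that eps is the
      # per-iteration step in [0,1] input-intensity units; dividing by the
      # per-channel sd expresses that step in the standardised input space
      gmax <- max(abs(g$dX))
      if (gmax > 0) {
        step <- config@eps * (g$dX / gmax)
        for (c in 1:3) step[, , c] <- step[, , c] / channelSd[c]
        X <- X + step
      }
      cache <- .nnForward(params, X)
      camSum <- camSum + .rawCam(params, cache, classIdx)
    }
  }
  list(camSum = camSum, logit0 = logit0,
       logitT = cache$logits[classIdx])
}

#' Adversarial-climbing activation map (AdvCAM)
#'
#' Iteratively perturbs the input along the gradient of
#' \eqn{L = y_c - \sum_{k \ne c} y_k - L_{restrict}}, where the restriction
#' term penalises changes of the activation map inside regions already highly
#' activated (above \code{maskThreshold} of the map maximum), so that the
#' ascent amplifies non-discriminative object regions instead of sharpening
#' the existing peak. The activation maps along the trajectory are summed and
#' the aggregate is upsampled and min-max normalised. With
#' \code{iterations = 0} the result equals [gradCAM()].
#'
#' @inheritParams gradCAM
#' @param config a [ClimbingConfig-class].
#' @param details logical; when TRUE, attach the start and end target logits
#'   as attributes \code{logit0} / \code{logitT}.
#' @return an [ActivationMap-class].
#' @export
adversarialClimb <- function(classifier, image, classId,
                             config = climbingConfig(), details = FALSE) {
  stopifnot(is(classifier, "ConvNetClassifier"), is(config, "ClimbingConfig"))
  validObject(config)
  idx <- .resolveClassId(classifier, classId)
  X0 <- .preprocess(classifier, image)
  tr <- .climbTrajectory(classifier@params, X0, idx, config,
                         channelSd = classifier@channelSd)
  d <- dim(image)
  out <- .finalizeCam(tr$camSum, d[1L], d[2L], idx)
  if (details) {
    attr(out, "logit0") <- tr$logit0
    attr(out, "logitT") <- tr$logitT
  }
  out
}

#' Binary-class refined activation map (background-subtracted AdvCAM)
#'
#' For a binary background/eardrum classifier, computes the AdvCAM of both
#' classes with identical settings and subtracts the weighted background map
#' from the foreground map,
#' \eqn{map = AdvCAM_{fg}(x) - \lambda \cdot AdvCAM_{bg}(x)},
#' clamping negatives to zero and min-max normalising the result. The
#' subtraction is done on the raw (unnormalised) aggregated maps: both are
#' gradient-weighted feature sums from the same backbone, hence in the same
#' units, and normalising each to \[0,1\] first would inflate the typically
#' weak background map on eardrum-present frames by orders of magnitude.
#' Background structure (canal wall, wax) activated in the background map
#' cancels, sharpening the eardrum boundary.
#'
#' @inheritParams adversarialClimb
#' @return an [ActivationMap-class] for the foreground (eardrum) class.
#' @export
bcAdvCAM <- function(classifier, image, config = climbingConfig()) {
  stopifnot(is(classifier, "ConvNetClassifier"), is(config, "ClimbingConfig"))
  validObject(config)
  if (length(classifier@classes) != 2L)
    stop("'classifier' must have a binary (background/eardrum) head; got ",
         length(classifier@classes), " classes", call. = FALSE)
  X0 <- .preprocess(classifier, image)
  trF <- .climbTrajectory(classifier@params, X0, 2L, config,
                          channelSd = classifier@channelSd)
  trB <- .climbTrajectory(classifier@params, X0, 1L, config,
                          channelSd = classifier@channelSd)
  d <- dim(image)
  upF <- .resizeBilinearMat(trF$camSum, d[1L], d[2L])
  upB <- .resizeBilinearMat(trB$camSum, d[1L], d[2L])
  v <- pmax(upF - config@bcLambda * upB, 0)
  new("ActivationMap", values = .normalize01(v), classId = 2L)
}

#' Binarise an activation map
#'
#' Pixels strictly above \code{tau} times the map maximum form the mask; an
#' all-zero map yields an all-zero mask.
#'
#' @param map an [ActivationMap-class] or a non-negative numeric matrix.
#' @param tau relative threshold in (0,1).
#' @return a logical matrix.
#' @export
thresholdMask <- function(map, tau = 0.5) {
  if (is(map, "ActivationMap")) map <- map@values
  if (!is.matrix(map)) stop("'map' must be a matrix or ActivationMap",
                            call. = FALSE)
  if (!is.finite(tau) || tau <= 0 || tau >= 1)
    stop("'tau' must lie strictly between 0 and 1", call. = FALSE)
  mx <- max(map)
  if (mx <= 0) return(matrix(FALSE, nrow(map), ncol(map)))
  map > tau * mx
}

#' Eardrum coverage score
#'
#' Fraction of frame pixels covered by the segmented eardrum:
#' \eqn{S_{edc} = \#\{mask\} / \#\{pixels\}}. The denominator is the whole
#' frame, not the field-of-view interior.
#'
#' @param mask a logical (or 0/1) matrix.
#' @return numeric(1) in \[0,1\].
#' @examples
#' m <- matrix(FALSE, 100, 100); m[1:50, 1:50] <- TRUE
#' coverageScore(m)  # 0.25
#' @export
coverageScore <- function(mask) {
  if (length(mask) == 0L) stop("empty mask", call. = FALSE)
  if (!is.matrix(mask)) stop("'mask' must be a matrix", call. = FALSE)
  sum(mask != 0) / length(mask)
}

#' Coverage of one frame via the binary activation-map pipeline
#'
#' Convenience composition used by the end-to-end pipeline: refined
#' activation map, relative-threshold binarisation, coverage score.
#'
#' @inheritParams bcAdvCAM
#' @return list with \code{sEdc} (numeric coverage), \code{mask} (logical
#'   matrix) and \code{map} (the [ActivationMap-class]).
#' @export
eardrumCoverage <- function(classifier, image, config = climbingConfig()) {
  map <- bcAdvCAM(classifier, image, config)
  mask <- thresholdMask(map, config@maskThreshold)
  list(sEdc = coverageScore(mask), mask = mask, map = map)
}
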