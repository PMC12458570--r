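#' Accessors for package classes
#'
#' Small accessor generics: slot access stays behind functions so internal
#' representations can change without breaking user code.
#'
#' @param object an object of the class the accessor documents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sigmaMax", function(object) standardGeneric("sigmaMax"))

#' @rdname accessors
#' @export
setGeneric("camValues", function(object) standardGeneric("camValues"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("frameImages", function(object) standardGeneric("frameImages"))

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(object) standardGeneric("frameIndex"))

#' @rdname accessors
#' @export
setGeneric("fovCenter", function(object) standardGeneric("fovCenter"))

#' @rdname accessors
#' @export
setGeneric("fovRadius", function(object) standardGeneric("fovRadius"))

#' @rdname accessors
#' @export
setGeneric("finalBlur", function(object) standardGeneric("finalBlur"))

#' @rdname accessors
setMethod("sigmaMax", "GmmFit", function(object) object@sigmaMax)

#' @rdname accessors
setMethod("sigmaMax", "ClarityResult", function(object) object@sigmaMax)

#' @rdname accessors
setMethod("camValues", "ActivationMap", function(object) object@values)

#' @rdname accessors
setMethod("classLabels", "ConvNetClassifier", function(object) object@classes)

#' @rdname accessors
setMethod("classLabels", "ImageDataset", function(object) object@labels)

#' @rdname accessors
setMethod("frameImages", "OtoFrames", function(object) object@frames)

#' @rdname accessors
setMethod("frameIndex", "OtoFrames", function(object) object@frameIndex)

#' @rdname accessors
setMethod("fovCenter", "FovCircle", function(object) c(object@x, object@y))

#' @rdname accessors
setMethod("fovRadius", "FovCircle", function(object) object@r)

#' @rdname accessors
setMethod("finalBlur", "ClarityResult", function(object) object@sBlf)

#' @describeIn accessors number of frames in the sequence.
#' @param x an [OtoFrames-class] object.
#' @export
setMethod("length", "OtoFrames", function(x) length(x@frames))

#' @describeIn accessors extract one frame image (a height x width x 3 array).
#' @param i frame position (1-based within the decoded sequence).
#' @param j,... unused.
#' @export
setMethod("[[", "OtoFrames", function(x, i, j, ...) x@frames[[i]])

setMethod("show", "FrameSpec", function(object) {
  cat(sprintf(
    "FrameSpec: %d x %d px, FOV r=%.1f at (%.1f, %.1f), visibility='%s', blur sigma=%.2g, seed=%d\n",
    object@imageSize[1L], object@imageSize[2L], object@fovRadius,
    object@fovCenter[1L], object@fovCenter[2L], object@visibility,
    object@blurSigma, object@textureSeed))
})

setMethod("show", "SyntheticFrame", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "SyntheticFrame: %d x %d px, visibility='%s', eardrum coverage %.3f, FOV coverage %.3f\n",
    d[1L], d[2L], object@spec@visibility,
    mean(object@eardrumMask), mean(object@fovMask)))
})

setMethod("show", "OtoFrames", function(object) {
  cat(sprintf("OtoFrames: %d frame(s) from '%s'\n",
              length(object@frames), object@source))
  if (length(object@frames)) {
    d <- dim(object@frames[[1L]])
    cat(sprintf("  %d x %d px, indices %s\n", d[1L], d[2L],
                paste(utils::head(object@frameIndex, 8L), collapse = ", ")))
  }
})

setMethod("show", "ConvNetClassifier", function(object) {
  cat(sprintf(
    "ConvNetClassifier: %d classes (%s), input %dx%d\n",
    length(object@classes), paste(object@classes, collapse = ", "),
    object@inputSize, object@inputSize))
  if (length(object@history$trainAccuracy))
    cat(sprintf("  final training accuracy %.3f over %d epoch(s)\n",
                utils::tail(object@history$trainAccuracy, 1L),
                length(object@history$trainAccuracy)))
})

setMethod("show", "ActivationMap", function(object) {
  cat(sprintf("ActivationMap: %d x %d, class %d, range [%.3f, %.3f]\n",
              nrow(object@values), ncol(object@values), object@classId,
              min(object@values), max(object@values)))
})

setMethod("show", "FovCircle", function(object) {
  cat(sprintf("FovCircle: centre (%.1f, %.1f), radius %.1f px, deltaL %.4f\n",
              object@x, object@y, object@r, object@deltaL))
})

setMethod("show", "GmmFit", function(object) {
  cat(sprintf(
    "GmmFit: means (%.4g, %.4g), sds (%.4g, %.4g), weights (%.3f, %.3f), sigmaMax %.4g%s\n",
    object@means[1L], object@means[2L], object@sds[1L], object@sds[2L],
    object@weights[1L], object@weights[2L], object@sigmaMax,
    if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "ClarityResult", function(object) {
  if (object@noFov) {
    cat("ClarityResult: no FOV detected, sBlf = 0\n")
  } else {
    cat(sprintf(
      "ClarityResult: sBl %.4g (sigmaMax %.4g / contrast %.4g), focus (%.0f, %.0f), sF %.1f, sBlf %.4g\n",
      object@sBl, object@sigmaMax, object@contrast,
      object@focusX, object@focusY, object@sF, object@sBlf))
  }
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: stride %d, topK %d, weights (view %.2f, coverage %.2f, blur %.2f), seed %d\n",
    object@stride, object@topK, object@weights[1L], object@weights[2L],
    object@weights[3L], object@seed))
})
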