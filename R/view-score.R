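# Eardrum view score: the 3-class (none / partial / full eardrum)
# probability vector of a frame, reduced to its expected eardrum-area score.

#' Predict eardrum-view class probabilities
#'
#' Runs the 3-class view classifier on a frame and returns the softmax class
#' probabilities in the package's fixed class order (none, partial, full).
#'
#' @param classifier a [ConvNetClassifier-class] trained with the 3-class
#'   view head.
#' @param image a height x width x 3 RGB array in \[0,1\].
#' @return named numeric(3) of probabilities (none, partial, full), summing
#'   to 1.
#' @seealso [eardrumViewScore()]
#' @export
predictView <- function(classifier, image) {
  stopifnot(is(classifier, "ConvNetClassifier"))
  if (!identical(classifier@classes, c("none", "partial", "full")))
    stop("'classifier' must have the 3-class view head ",
         "(classes none, partial, full); got: ",
         paste(classifier@classes, collapse = ", "), call. = FALSE)
  predictProbs(classifier, image)
}

#' Eardrum view score
#'
#' The expected eardrum-area score of a frame under the classifier's
#' predicted class probabilities, with area scores 1.0 (full eardrum),
#' 0.5 (partial eardrum) and 0.0 (no eardrum):
#' \deqn{S_{edv} = P_{full} \cdot 1 + P_{partial} \cdot 0.5 + P_{none} \cdot 0.}
#' Higher values indicate a more complete, more diagnostically relevant view.
#'
#' @param probs numeric(3) of class probabilities. A named vector is matched
#'   by name (\code{none}, \code{partial}, \code{full}); an unnamed vector is
#'   taken in that order. Must be non-negative and sum to 1 within 1e-6.
#' @return numeric(1), the view score in \[0,1\].
#' @examples
#' eardrumViewScore(c(none = 0.1, partial = 0.3, full = 0.6))  # 0.75
#' @export
eardrumViewScore <- function(probs) {
  if (length(probs) != 3L)
    stop("'probs' must have 3 elements (none, partial, full)", call. = FALSE)
  if (!is.null(names(probs))) {
    if (!setequal(names(probs), c("none", "partial", "full")))
      stop("named 'probs' must use names none, partial, full", call. = FALSE)
    probs <- probs[c("none", "partial", "full")]
  }
  if (any(!is.finite(probs)) || any(probs < -1e-9))
    stop("'probs' must be finite and non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-6)
    stop("'probs' must sum to 1 (got ", format(sum(probs)), ")",
         call. = FALSE)
  unname(probs[3L] * 1 + probs[2L] * 0.5 + probs[1L] * 0)
}
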