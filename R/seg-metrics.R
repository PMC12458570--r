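# Segmentation evaluation metrics used to compare activation-map variants
# against ground-truth masks: pixelwise confusion metrics, rank-based AUROC
# of a continuous map, and the boundary distances (Hausdorff, mean absolute
# boundary deviation). Boundaries are the 8-connected erosion difference;
# pixels outside the image count as background.

.asBinary <- function(mask, name) {
  if (!is.matrix(mask)) stop("'", name, "' must be a matrix", call. = FALSE)
  mask != 0
}

#' Pixelwise confusion metrics
#'
#' IoU, Dice coefficient, accuracy, sensitivity and specificity of a
#' predicted binary mask against the ground truth. Conventions for empty
#' masks: when both masks are empty, IoU = DSC = 1 (perfect agreement);
#' sensitivity is 1 when the truth has no positives, specificity is 1 when
#' it has no negatives (vacuous truth).
#'
#' @param pred,truth binary matrices of equal shape.
#' @return named numeric: \code{iou}, \code{dsc}, \code{acc}, \code{sen},
#'   \code{spe}.
#' @examples
#' p <- matrix(c(1, 0, 1, 0), 2); t <- matrix(c(1, 0, 0, 0), 2)
#' confusionMetrics(p, t)
#' @export
confusionMetrics <- function(pred, truth) {
  pred <- .asBinary(pred, "pred"); truth <- .asBinary(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("'pred' and 'truth' must have the same shape", call. = FALSE)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  un <- tp + fp + fn
  c(iou = if (un == 0) 1 else tp / un,
    dsc = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    acc = (tp + tn) / length(pred),
    sen = if (tp + fn == 0) 1 else tp / (tp + fn),
    spe = if (tn + fp == 0) 1 else tn / (tn + fp))
}

#' AUROC of a continuous activation map
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of the map values
#' against the pixel labels; invariant under any strictly monotone transform
#' of the map.
#'
#' @param map an [ActivationMap-class] or numeric matrix.
#' @param truth binary matrix of the same shape with both classes present.
#' @return numeric(1) in \[0,1\].
#' @export
aurocFromMap <- function(map, truth) {
  if (is(map, "ActivationMap")) map <- map@values
  truth <- .asBinary(truth, "truth")
  if (!identical(dim(map), dim(truth)))
    stop("'map' and 'truth' must have the same shape", call. = FALSE)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("'truth' must contain both classes", call. = FALSE)
  r <- rank(as.vector(map))
  (sum(r[as.vector(truth)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Boundary pixels: mask pixels with at least one 8-neighbour (or the image
# border) outside the mask. Returns an n x 2 matrix of 0-based (x, y).
.boundaryPixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  allNb <- matrix(TRUE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    allNb <- allNb & pad[(1:h) + 1L + dy, (1:w) + 1L + dx]
  }
  idx <- which(mask & !allNb, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}

# Directed distances: for each point of `a`, Euclidean distance to the
# nearest point of `b`.
.nearestDistances <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  sqrt(apply(d2, 1L, min))
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric Hausdorff distance (Euclidean) between the 8-connected boundary
#' pixel sets of two non-empty masks.
#'
#' @param pred,truth non-empty binary matrices of equal shape.
#' @return numeric(1) in px.
#' @export
hausdorffDistance <- function(pred, truth) {
  pred <- .asBinary(pred, "pred"); truth <- .asBinary(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("'pred' and 'truth' must have the same shape", call. = FALSE)
  if (!any(pred) || !any(truth))
    stop("Hausdorff distance is undefined for an empty mask", call. = FALSE)
  bp <- .boundaryPixels(pred); bt <- .boundaryPixels(truth)
  max(max(.nearestDistances(bp, bt)), max(.nearestDistances(bt, bp)))
}

#' Mean absolute boundary deviation
#'
#' Mean, over the predicted mask's boundary pixels, of the Euclidean
#' distance to the nearest ground-truth boundary pixel (directed mean
#' boundary deviation, px). Always bounded above by the Hausdorff distance
#' of the same pair.
#'
#' @inheritParams hausdorffDistance
#' @return numeric(1) in px.
#' @export
meanAbsDeviation <- function(pred, truth) {
  pred <- .asBinary(pred, "pred"); truth <- .asBinary(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("'pred' and 'truth' must have the same shape", call. = FALSE)
  if (!any(pred) || !any(truth))
    stop("mean boundary deviation is undefined for an empty mask",
         call. = FALSE)
  mean(.nearestDistances(.boundaryPixels(pred), .boundaryPixels(truth)))
}

#' Batch segmentation evaluation
#'
#' Evaluates a list of predicted masks (and optionally the continuous maps
#' they were thresholded from) against ground-truth masks, one row per
#' image plus mean/sd summary rows.
#'
#' @param preds list of binary matrices.
#' @param truths list of binary matrices, same length and shapes.
#' @param maps optional list of [ActivationMap-class]/matrices for AUROC.
#' @return an [S4Vectors::DataFrame-class] with columns \code{image},
#'   \code{iou}, \code{dsc}, \code{acc}, \code{sen}, \code{spe}, optionally
#'   \code{auroc}, and \code{hd}, \code{mad} (NA where undefined on empty
#'   masks); the last two rows hold the mean and standard deviation.
#' @export
evaluateSegmentation <- function(preds, truths, maps = NULL) {
  stopifnot(length(preds) == length(truths))
  n <- length(preds)
  rows <- lapply(seq_len(n), function(i) {
    cm <- confusionMetrics(preds[[i]], truths[[i]])
    hd <- mad <- NA_real_
    if (any(preds[[i]] != 0) && any(truths[[i]] != 0)) {
      hd <- hausdorffDistance(preds[[i]], truths[[i]])
      mad <- meanAbsDeviation(preds[[i]], truths[[i]])
    }
    au <- if (!is.null(maps)) aurocFromMap(maps[[i]], truths[[i]]) else NA_real_
    c(cm, auroc = au, hd = hd, mad = mad)
  })
  tab <- do.call(rbind, rows)
  out <- S4Vectors::DataFrame(image = c(as.character(seq_len(n)), "mean", "sd"))
  for (cn in colnames(tab)) {
    v <- tab[, cn]
    out[[cn]] <- c(v, mean(v, na.rm = TRUE), stats::sd(v[!is.na(v)]))
  }
  if (is.null(maps)) out$auroc <- NULL
  out
}
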