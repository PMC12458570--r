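# Compact CNN: conv3x3 -> ReLU -> avgpool2 -> conv3x3 -> ReLU -> global
# average pooling -> linear head. Implemented with im2col matrix products so
# the backward pass can return exact gradients w.r.t. the last convolutional
# feature maps (Grad-CAM) and w.r.t. the input image (adversarial climbing).
#
# Feature arrays are [height, width, channels]; im2col matrices are
# (h*w) x (9*channels) with columns ordered channel-major, then the nine
# kernel offsets in (dy, dx) row-major order.

.im2col <- function(X) {
  d <- dim(X); h <- d[1L]; w <- d[2L]; cin <- d[3L]
  Xp <- array(0, c(h + 2L, w + 2L, cin))
  Xp[2:(h + 1L), 2:(w + 1L), ] <- X
  P <- matrix(0, h * w, 9L * cin)
  col <- 0L
  for (ci in seq_len(cin)) for (dy in -1:1) for (dx in -1:1) {
    col <- col + 1L
    P[, col] <- as.vector(Xp[(1:h) + 1L + dy, (1:w) + 1L + dx, ci])
  }
  P
}

.col2im <- function(dP, h, w, cin) {
  dXp <- array(0, c(h + 2L, w + 2L, cin))
  col <- 0L
  for (ci in seq_len(cin)) for (dy in -1:1) for (dx in -1:1) {
    col <- col + 1L
    rows <- (1:h) + 1L + dy; cols <- (1:w) + 1L + dx
    dXp[rows, cols, ci] <- dXp[rows, cols, ci] + matrix(dP[, col], h, w)
  }
  dXp[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

.avgPool2 <- function(A) {
  d <- dim(A); h <- d[1L]; w <- d[2L]
  (A[seq(1L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
   A[seq(2L, h, 2L), seq(1L, w, 2L), , drop = FALSE] +
   A[seq(1L, h, 2L), seq(2L, w, 2L), , drop = FALSE] +
   A[seq(2L, h, 2L), seq(2L, w, 2L), , drop = FALSE]) / 4
}

.avgUnpool2 <- function(dP) {
  d <- dim(dP); h2 <- d[1L]; w2 <- d[2L]
  dA <- array(0, c(2L * h2, 2L * w2, d[3L]))
  q <- dP / 4
  dA[seq(1L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), ] <- q
  dA[seq(2L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), ] <- q
  dA[seq(1L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), ] <- q
  dA[seq(2L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), ] <- q
  dA
}

.nnInit <- function(nClasses, nf1 = 8L, nf2 = 16L, cin = 3L) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  list(W1 = he(9L * cin, nf1), b1 = numeric(nf1),
       W2 = he(9L * nf1, nf2), b2 = numeric(nf2),
       Wd = he(nf2, nClasses) / sqrt(2), bd = numeric(nClasses))
}

# Forward pass; the cache carries everything the backward pass needs.
.nnForward <- function(params, X) {
  d <- dim(X); h <- d[1L]; w <- d[2L]
  P1 <- .im2col(X)
  Z1 <- sweep(P1 %*% params$W1, 2L, params$b1, "+")
  A1 <- Z1 * (Z1 > 0)
  Pool <- .avgPool2(array(A1, c(h, w, ncol(Z1))))
  h2 <- dim(Pool)[1L]; w2 <- dim(Pool)[2L]
  P2 <- .im2col(Pool)
  Z2 <- sweep(P2 %*% params$W2, 2L, params$b2, "+")
  A2 <- Z2 * (Z2 > 0)                      # (h2*w2) x nf2, the CAM features
  gap <- colMeans(A2)
  logits <- drop(gap %*% params$Wd) + params$bd
  list(P1 = P1, Z1 = Z1, P2 = P2, Z2 = Z2, A2 = A2, gap = gap,
       logits = logits, h = h, w = w, h2 = h2, w2 = w2)
}

# Backward pass. `dlogits` seeds the head; `dA2extra` (optional, same shape
# as cache$A2) injects an additional gradient on the feature maps, used by
# the activation-map regularisation term. Returns weight gradients and,
# when wrtInput, the gradient w.r.t. the input image.
.nnBackward <- function(params, cache, dlogits, wrtInput = FALSE,
                        dA2extra = NULL, weightGrads = TRUE) {
  n2 <- cache$h2 * cache$w2
  nf2 <- ncol(cache$Z2); nf1 <- ncol(cache$Z1)
  dgap <- drop(params$Wd %*% dlogits)
  dA2 <- matrix(dgap / n2, n2, nf2, byrow = TRUE)
  if (!is.null(dA2extra)) dA2 <- dA2 + dA2extra
  dZ2 <- dA2 * (cache$Z2 > 0)
  dP2 <- dZ2 %*% t(params$W2)
  dPool <- .col2im(dP2, cache$h2, cache$w2, nf1)
  dA1 <- matrix(.avgUnpool2(dPool), cache$h * cache$w, nf1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  out <- list()
  if (weightGrads) {
    out$dWd <- outer(cache$gap, dlogits); out$dbd <- dlogits
    out$dW2 <- crossprod(cache$P2, dZ2); out$db2 <- colSums(dZ2)
    out$dW1 <- crossprod(cache$P1, dZ1); out$db1 <- colSums(dZ1)
  }
  if (wrtInput) {
    dP1 <- dZ1 %*% t(params$W1)
    out$dX <- .col2im(dP1, cache$h, cache$w, 3L)
  }
  out
}

.softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

.preprocess <- function(classifier, image) {
  .assertImage(image)
  s <- classifier@inputSize
  X <- .resizeBilinearImg(image, s, s)
  for (c in 1:3)
    X[, , c] <- (X[, , c] - classifier@channelMean[c]) / classifier@channelSd[c]
  X
}

.adamStep <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[paste0("d", nm)]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.canonicalClassOrder <- function(levels) {
  if (setequal(levels, c("none", "partial", "full"))) c("none", "partial", "full")
  else if (setequal(levels, c("absent", "present"))) c("absent", "present")
  else sort(levels)
}

#' Train the compact view classifier
#'
#' Trains the package's compact CNN on a labelled [ImageDataset-class].
#' Images are resized to \code{inputSize} and normalised per channel with
#' statistics of the training images; optimisation is cross-entropy with
#' Adam, and the weights with the best validation accuracy are kept.
#' Training is deterministic for a fixed \code{seed}.
#'
#' The same routine trains both heads used by the pipeline: the 3-class
#' eardrum-view head (\code{none}/\code{partial}/\code{full}) and the binary
#' head (\code{absent}/\code{present}) behind the activation-map coverage
#' stage. Class order is fixed at (none, partial, full), respectively
#' (absent, present), in all outputs.
#'
#' @param dataset an [ImageDataset-class]; every class must have at least two
#'   images.
#' @param inputSize side length (px) images are resized to before the network.
#' @param epochs,batchSize,lr Adam training schedule.
#' @param valFraction fraction of images held out (stratified) for checkpoint
#'   selection; when the split would leave a class empty, selection falls
#'   back to training accuracy.
#' @param nf1,nf2 channel widths of the two convolution blocks.
#' @param seed integer seed covering initialisation and epoch shuffling.
#' @return a [ConvNetClassifier-class].
#' @examples
#' ds <- generateShapesDataset(24, seed = 1)
#' clf <- trainViewClassifier(ds, epochs = 2, seed = 1)
#' classLabels(clf)
#' @export
trainViewClassifier <- function(dataset, inputSize = 64L, epochs = 45L,
                                batchSize = 8L, lr = 1e-2,
                                valFraction = 0.15, nf1 = 8L, nf2 = 16L,
                                seed = 1L) {
  stopifnot(is(dataset, "ImageDataset"))
  labels <- as.character(dataset@labels)
  classes <- .canonicalClassOrder(levels(dataset@labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stop("every class needs at least 2 images; got counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  inputSize <- as.integer(inputSize)
  if (inputSize %% 4L != 0L) stop("'inputSize' must be a multiple of 4")

  .withSeed(seed, {
    n <- length(dataset@images)
    Xs <- lapply(dataset@images, .resizeBilinearImg, h2 = inputSize,
                 w2 = inputSize)
    chMean <- chSd <- numeric(3)
    for (c in 1:3) {
      v <- unlist(lapply(Xs, function(x) as.vector(x[, , c])))
      chMean[c] <- mean(v); chSd[c] <- max(stats::sd(v), 1e-6)
    }
    for (i in seq_len(n)) for (c in 1:3)
      Xs[[i]][, , c] <- (Xs[[i]][, , c] - chMean[c]) / chSd[c]
    y <- match(labels, classes)

    # stratified validation split
    valIdx <- integer()
    for (k in seq_along(classes)) {
      ik <- which(y == k)
      nv <- floor(valFraction * length(ik))
      if (nv >= 1L && length(ik) - nv >= 2L)
        valIdx <- c(valIdx, sample(ik, nv))
    }
    trainIdx <- setdiff(seq_len(n), valIdx)
    useVal <- length(valIdx) >= length(classes)

    params <- .nnInit(length(classes), nf1 = nf1, nf2 = nf2)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    tstep <- 0L
    accuracyOn <- function(idx) {
      pred <- vapply(idx, function(i)
        which.max(.nnForward(params, Xs[[i]])$logits), integer(1))
      mean(pred == y[idx])
    }
    bestAcc <- -1; bestTrainAcc <- -1; bestParams <- params
    histTrain <- histVal <- numeric()
    for (ep in seq_len(epochs)) {
      lrEp <- lr * 0.5^((ep - 1L) %/% 20L)   # step decay stabilises late epochs
      ord <- sample(trainIdx)
      for (b0 in seq(1L, length(ord), by = batchSize)) {
        batch <- ord[b0:min(b0 + batchSize - 1L, length(ord))]
        grads <- NULL
        for (i in batch) {
          cache <- .nnForward(params, Xs[[i]])
          p <- .softmax(cache$logits)
          dlog <- p; dlog[y[i]] <- dlog[y[i]] - 1
          g <- .nnBackward(params, cache, dlog)
          if (is.null(grads)) grads <- g
          else for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(batch)
        tstep <- tstep + 1L
        upd <- .adamStep(params, grads, state, lrEp, tstep)
        params <- upd$params; state <- upd$state
      }
      accT <- accuracyOn(trainIdx)
      accV <- if (useVal) accuracyOn(valIdx) else accT
      histTrain <- c(histTrain, accT); histVal <- c(histVal, accV)
      # ties on the (small) validation set are broken by training accuracy
      if (accV > bestAcc || (accV == bestAcc && accT > bestTrainAcc)) {
        bestAcc <- accV; bestTrainAcc <- accT; bestParams <- params
      }
    }

    new("ConvNetClassifier",
        params = bestParams, classes = classes, inputSize = inputSize,
        channelMean = chMean, channelSd = chSd,
        config = list(epochs = epochs, batchSize = batchSize, lr = lr,
                      valFraction = valFraction, nf1 = nf1, nf2 = nf2,
                      seed = as.integer(seed)),
        history = list(trainAccuracy = histTrain, valAccuracy = histVal))
  })
}

#' Class logits and probabilities for one frame
#'
#' @param classifier a trained [ConvNetClassifier-class].
#' @param image a height x width x 3 RGB array in \[0,1\].
#' @return `classifierLogits`: a named numeric vector of class logits.
#'   `predictProbs`: the softmax of the logits (sums to 1).
#' @export
classifierLogits <- function(classifier, image) {
  X <- .preprocess(classifier, image)
  z <- .nnForward(classifier@params, X)$logits
  names(z) <- classifier@classes
  z
}

#' @rdname classifierLogits
#' @export
predictProbs <- function(classifier, image) {
  z <- classifierLogits(classifier, image)
  p <- .softmax(z)
  names(p) <- classifier@classes
  p
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is an R-native serialisation of the classifier; a JSON
#' sidecar (written when \pkg{jsonlite} is available) records the class
#' order and preprocessing so the file is self-describing.
#'
#' @param classifier a [ConvNetClassifier-class].
#' @param path checkpoint file path (the sidecar gets extension
#'   \code{.json}).
#' @return `loadClassifier` returns the [ConvNetClassifier-class].
#' @export
saveClassifier <- function(classifier, path) {
  saveRDS(classifier, path)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(classes = classifier@classes,
                 inputSize = classifier@inputSize,
                 channelMean = classifier@channelMean,
                 channelSd = classifier@channelSd)
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "ConvNetClassifier"))
  obj
}
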