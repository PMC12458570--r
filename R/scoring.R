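# Rank fusion of the three per-frame scores into the informative score, and
# top-k selection. All three raw scores are better-when-larger, rank 1 goes
# to the largest value, and the fused score is a weighted rank sum -- so a
# SMALLER informative score marks a MORE informative frame.

#' Rank raw scores (1 = best)
#'
#' Assigns rank 1 to the largest raw score; ties receive the average of the
#' tied positions.
#'
#' @param values numeric vector of finite raw scores (all three per-frame
#'   scores are better-when-larger).
#' @return numeric vector of ranks in \[1, n\], possibly non-integer on ties.
#' @examples
#' rankScores(c(0.9, 0.1, 0.5))  # 1 3 2
#' rankScores(c(0.5, 0.5))       # 1.5 1.5
#' @export
rankScores <- function(values) {
  if (!length(values)) stop("'values' must be non-empty", call. = FALSE)
  if (any(!is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  length(values) + 1 - rank(values, ties.method = "average")
}

#' Informative score by weighted rank fusion
#'
#' Fuses the per-frame ranks of the three scores into
#' \deqn{S_I = 0.4 \, Rank(S_{edv}) + 0.2 \, Rank(S_{edc}) + 0.4 \, Rank(S_{blf}),}
#' with configurable non-negative weights summing to 1. A smaller
#' informative score marks a more diagnostically informative frame.
#'
#' @param scores a data.frame or [S4Vectors::DataFrame-class] with columns
#'   \code{s_edv}, \code{s_edc}, \code{s_blf} (and optionally
#'   \code{frame_index}; one is created if absent).
#' @param weights numeric(3) fusion weights for (view, coverage, blur).
#' @return the input with columns \code{rank_edv}, \code{rank_edc},
#'   \code{rank_blf} and \code{s_i} appended.
#' @examples
#' informativeScore(data.frame(s_edv = c(1, .5), s_edc = c(.2, .1),
#'                             s_blf = c(3, 9)))
#' @export
informativeScore <- function(scores, weights = c(0.4, 0.2, 0.4)) {
  need <- c("s_edv", "s_edc", "s_blf")
  if (!all(need %in% colnames(scores)))
    stop("'scores' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must be 3 non-negative values summing to 1",
         call. = FALSE)
  if (!"frame_index" %in% colnames(scores))
    scores$frame_index <- seq_len(nrow(scores)) - 1L
  scores$rank_edv <- rankScores(scores$s_edv)
  scores$rank_edc <- rankScores(scores$s_edc)
  scores$rank_blf <- rankScores(scores$s_blf)
  scores$s_i <- weights[1L] * scores$rank_edv +
    weights[2L] * scores$rank_edc + weights[3L] * scores$rank_blf
  scores
}

#' Select the top-k most informative frames
#'
#' Returns the \code{k} frames with the smallest informative score, in
#' ascending order; ties are broken by the larger view score, then by the
#' smaller frame index.
#'
#' @param scores output of [informativeScore()] (must contain \code{s_i},
#'   \code{s_edv} and \code{frame_index}).
#' @param k number of frames to select, \code{1 <= k <= nrow(scores)}.
#' @return integer vector of \code{k} frame indices.
#' @export
selectTopK <- function(scores, k) {
  need <- c("s_i", "s_edv", "frame_index")
  if (!all(need %in% colnames(scores)))
    stop("'scores' must have columns ", paste(need, collapse = ", "),
         "; run informativeScore() first", call. = FALSE)
  n <- nrow(scores)
  if (!is.finite(k) || k < 1 || k > n)
    stop("'k' must lie in 1..", n, call. = FALSE)
  ord <- order(scores$s_i, -scores$s_edv, scores$frame_index)
  scores$frame_index[ord[seq_len(k)]]
}
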