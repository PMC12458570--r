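# End-to-end orchestration: decode frames, score each on the three axes
# (view, coverage, clarity), fuse by weighted rank, select the top-k frames,
# and write the score table, the selected stills and a run manifest.

#' Pipeline configuration constructor
#'
#' @param stride temporal subsampling (keep frame indices divisible by it).
#' @param topK number of frames to select.
#' @param weights rank-fusion weights (view, coverage, blur); non-negative,
#'   summing to 1. Defaults 0.4 / 0.2 / 0.4.
#' @param cam a [ClimbingConfig-class] for the coverage stage.
#' @param sigmaSmooth,deltaR,radiusRange,eps clarity-stage settings, see
#'   [clarityScore()].
#' @param seed integer seed for every stochastic step.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(stride = 1L, topK = 4L,
                           weights = c(view = 0.4, coverage = 0.2, blur = 0.4),
                           cam = climbingConfig(), sigmaSmooth = 2,
                           deltaR = 5, radiusRange = c(0.25, 0.60),
                           eps = 1e-6, seed = 1L) {
  new("PipelineConfig", stride = as.integer(stride), topK = as.integer(topK),
      weights = as.numeric(weights), cam = cam,
      clarity = list(sigmaSmooth = sigmaSmooth, deltaR = deltaR,
                     radiusRange = radiusRange, eps = eps),
      seed = as.integer(seed))
}

#' Score every frame and select the most informative ones
#'
#' Runs the full flow on a video (path or [OtoFrames-class]): per frame, the
#' eardrum view score from the 3-class classifier, the coverage score from
#' the background-subtracted climbing activation map of the binary
#' classifier, and the clarity score; then weighted-rank fusion into the
#' informative score and top-k selection. Frames whose FOV detection fails
#' are kept with a final blur score of 0 (and logged in the manifest), so
#' rank denominators stay consistent and a degenerate frame never crashes a
#' run. Identical input and configuration yield an identical score table.
#'
#' @param input video path (multi-page TIFF or PNG directory) or an
#'   [OtoFrames-class].
#' @param viewClassifier 3-class [ConvNetClassifier-class]
#'   (none/partial/full).
#' @param binaryClassifier binary [ConvNetClassifier-class]
#'   (absent/present) for the coverage stage.
#' @param config a [PipelineConfig-class].
#' @param outDir optional output directory; when given, writes
#'   \code{scores.csv}, the selected frames as
#'   \code{<stem>_rank<r>_frame<idx>.png}, and \code{manifest.json} (when
#'   \pkg{jsonlite} is available).
#' @return an [S4Vectors::DataFrame-class] with one row per scored frame:
#'   \code{frame_index}, the three raw scores, their ranks, \code{s_i} and
#'   \code{selected}; metadata holds \code{selected} (ordered indices),
#'   \code{timings} and \code{failures}.
#' @export
runPipeline <- function(input, viewClassifier, binaryClassifier,
                        config = pipelineConfig(), outDir = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  frames <- if (is(input, "OtoFrames")) input
            else readFrames(input, stride = config@stride)
  n <- length(frames@frames)
  if (n == 0L) stop("no frames to score", call. = FALSE)
  if (config@topK > n)
    stop("'topK' (", config@topK, ") exceeds the number of frames (", n, ")",
         call. = FALSE)

  cl <- config@clarity
  sEdv <- sEdc <- sBlf <- numeric(n)
  noFov <- logical(n)
  timings <- c(view = 0, coverage = 0, clarity = 0)
  for (i in seq_len(n)) {
    img <- frames@frames[[i]]
    t0 <- proc.time()[["elapsed"]]
    sEdv[i] <- eardrumViewScore(predictView(viewClassifier, img))
    t1 <- proc.time()[["elapsed"]]
    sEdc[i] <- eardrumCoverage(binaryClassifier, img, config@cam)$sEdc
    t2 <- proc.time()[["elapsed"]]
    res <- clarityScore(img, sigmaSmooth = cl$sigmaSmooth, deltaR = cl$deltaR,
                        radiusRange = cl$radiusRange, eps = cl$eps,
                        seed = config@seed)
    t3 <- proc.time()[["elapsed"]]
    sBlf[i] <- res@sBlf
    noFov[i] <- res@noFov
    timings <- timings + c(view = t1 - t0, coverage = t2 - t1,
                           clarity = t3 - t2)
  }

  tab <- data.frame(frame_index = frames@frameIndex,
                    s_edv = sEdv, s_edc = sEdc, s_blf = sBlf)
  tab <- informativeScore(tab, weights = config@weights)
  sel <- selectTopK(tab, config@topK)
  tab$selected <- tab$frame_index %in% sel

  out <- S4Vectors::DataFrame(tab)
  S4Vectors::metadata(out) <- list(
    selected = sel,
    failures = frames@frameIndex[noFov],
    timings = timings,
    seed = config@seed)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
      stop("unwritable output directory: ", outDir, call. = FALSE)
    utils::write.csv(tab, file.path(outDir, "scores.csv"), row.names = FALSE)
    stem <- if (is(input, "OtoFrames") || dir.exists(as.character(input)[1]))
      basename(frames@source)
    else sub("\\.[^.]+$", "", basename(as.character(input)))
    if (identical(stem, "") || is.na(stem)) stem <- "video"
    for (r in seq_along(sel)) {
      pos <- match(sel[r], frames@frameIndex)
      png::writePNG(frames@frames[[pos]],
                    file.path(outDir, sprintf("%s_rank%d_frame%d.png",
                                              stem, r, sel[r])))
    }
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      manifest <- list(
        n_frames = n, selected = sel, failures = frames@frameIndex[noFov],
        seed = config@seed, stride = config@stride, top_k = config@topK,
        weights = as.numeric(config@weights),
        cam = list(eps = config@cam@eps, iterations = config@cam@iterations,
                   lambdaRestrict = config@cam@lambdaRestrict,
                   maskThreshold = config@cam@maskThreshold,
                   bcLambda = config@cam@bcLambda),
        clarity = cl, timings = as.list(round(timings, 3)))
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
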