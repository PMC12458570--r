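# Decoding frames from lossless containers (multi-page TIFF) or directories
# of still images, and the grayscale conversion used by the clarity stage.

.asRgbArray <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) {
    array(rep(x, 3L), c(d, 3L))
  } else if (d[3L] >= 3L) {
    x[, , 1:3, drop = FALSE]
  } else {
    array(rep(x[, , 1L], 3L), c(d[1:2], 3L))
  }
}

#' Read video frames
#'
#' Decodes a frame sequence from a multi-page TIFF container or a directory
#' of PNG stills (sorted lexicographically). Frames are returned in temporal
#' order as floating-point RGB arrays in \[0,1\]; \code{stride = k} keeps
#' frames whose original index is congruent to 0 modulo k, and the original
#' index is preserved in the metadata.
#'
#' @param path a \code{.tif}/\code{.tiff} file or a directory containing
#'   PNG frames.
#' @param stride integer >= 1, temporal subsampling factor.
#' @return an [OtoFrames-class].
#' @examples
#' vid <- designBestFrameVideo(seed = 1, n = 3, imageSize = c(64L, 64L))
#' path <- file.path(tempdir(), "demo.tiff")
#' generateVideo(vid$specs, path)
#' length(readFrames(path))
#' @export
readFrames <- function(path, stride = 1L) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    stop("'stride' must be an integer >= 1", call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (!length(files)) {
      if (length(list.files(path, pattern = "\\.jpe?g$", ignore.case = TRUE)))
        stop("JPEG stills are not supported; provide PNG frames",
             call. = FALSE)
      stop("empty directory: no PNG frames found in ", path, call. = FALSE)
    }
    frames <- lapply(files, function(f) .asRgbArray(png::readPNG(f)))
  } else if (file.exists(path)) {
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
      stop("unreadable container: expected a .tif/.tiff file or a directory ",
           "of PNG frames, got ", path, call. = FALSE)
    raw <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(raw)) raw <- list(raw)
    frames <- lapply(raw, .asRgbArray)
  } else {
    stop("no such file or directory: ", path, call. = FALSE)
  }
  idx <- seq_along(frames) - 1L
  keep <- idx %% stride == 0L
  new("OtoFrames",
      frames = lapply(frames[keep], .clip01),
      frameIndex = idx[keep],
      timestamp = rep(NA_real_, sum(keep)),
      source = path)
}

#' Convert an RGB frame to luminance
#'
#' BT.601 luma: \code{0.299 R + 0.587 G + 0.114 B}. Grayscale input (a
#' matrix, or RGB with equal channels) passes through unchanged.
#'
#' @param image a height x width x 3 array in \[0,1\], or a matrix.
#' @return a luminance matrix in \[0,1\].
#' @examples
#' toGrayscale(array(c(1, 0, 0), c(1, 1, 3)))  # pure red -> 0.299
#' @export
toGrayscale <- function(image) {
  if (is.matrix(image)) return(image)
  .assertImage(image)
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Write frames as PNG stills
#'
#' @param frames an [OtoFrames-class] or list of RGB arrays.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; files are named
#'   \code{<prefix>_frame<index>.png}.
#' @return invisibly, the written file paths.
#' @export
writeFramesPNG <- function(frames, dir, prefix = "frame") {
  if (is(frames, "OtoFrames")) {
    idx <- frames@frameIndex
    imgs <- frames@frames
  } else {
    imgs <- frames
    idx <- seq_along(imgs) - 1L
  }
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("unwritable path: ", dir, call. = FALSE)
  paths <- character(length(imgs))
  for (i in seq_along(imgs)) {
    paths[i] <- file.path(dir, sprintf("%s_frame%04d.png", prefix, idx[i]))
    png::writePNG(.clip01(imgs[[i]]), paths[i])
  }
  invisible(paths)
}
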