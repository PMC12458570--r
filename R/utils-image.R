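# Internal raster helpers. Images are numeric arrays [height, width, 3] in
# [0,1]; grayscale frames are plain matrices. Pixel coordinates are 0-based
# (x, y) = (column, row), origin top-left.

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Evaluate `expr` under a temporary RNG state; the caller's stream is
# untouched, so generators are pure functions of their seed.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# m[i + dy, j + dx] with replicated edges (dy, dx may be negative).
.shiftReplicate <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[pmin(pmax(seq_len(h) + dy, 1L), h), pmin(pmax(seq_len(w) + dx, 1L), w),
    drop = FALSE]
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding; `m` a matrix.
.gaussBlurMat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- .gaussKernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * .shiftReplicate(m, i - r - 1L, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * .shiftReplicate(m2, 0L, i - r - 1L)
  out
}

.gaussBlurImg <- function(img, sigma) {
  if (sigma <= 0) return(img)
  for (c in seq_len(dim(img)[3L]))
    img[, , c] <- .gaussBlurMat(img[, , c], sigma)
  img
}

# Signed 3x3 Sobel responses, scaled by 1/4 so a unit step edge yields a
# peak response of 1. gx is the horizontal derivative (along columns / x).
.sobel <- function(gray) {
  s <- function(dy, dx) .shiftReplicate(gray, dy, dx)
  gx <- (s(-1L, 1L) + 2 * s(0L, 1L) + s(1L, 1L) -
         s(-1L, -1L) - 2 * s(0L, -1L) - s(1L, -1L)) / 4
  gy <- (s(1L, -1L) + 2 * s(1L, 0L) + s(1L, 1L) -
         s(-1L, -1L) - 2 * s(-1L, 0L) - s(-1L, 1L)) / 4
  list(gx = gx, gy = gy)
}

# 4-neighbour Laplacian with replicate padding.
.laplacian <- function(gray) {
  .shiftReplicate(gray, 1L, 0L) + .shiftReplicate(gray, -1L, 0L) +
    .shiftReplicate(gray, 0L, 1L) + .shiftReplicate(gray, 0L, -1L) - 4 * gray
}

# Bilinear resize of a matrix to h2 x w2 (half-pixel centre alignment).
.resizeBilinearMat <- function(m, h2, w2) {
  h <- nrow(m); w <- ncol(m)
  if (h == h2 && w == w2) return(m)
  ys <- pmin(pmax((seq_len(h2) - 0.5) * h / h2 - 0.5, 0), h - 1)
  xs <- pmin(pmax((seq_len(w2) - 0.5) * w / w2 - 0.5, 0), w - 1)
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  y0 <- y0 + 1L; y1 <- y1 + 1L; x0 <- x0 + 1L; x1 <- x1 + 1L
  top <- sweep(m[y0, x0, drop = FALSE], 2L, 1 - fx, "*") +
         sweep(m[y0, x1, drop = FALSE], 2L, fx, "*")
  bot <- sweep(m[y1, x0, drop = FALSE], 2L, 1 - fx, "*") +
         sweep(m[y1, x1, drop = FALSE], 2L, fx, "*")
  sweep(top, 1L, 1 - fy, "*") + sweep(bot, 1L, fy, "*")
}

.resizeBilinearImg <- function(img, h2, w2) {
  out <- array(0, c(h2, w2, dim(img)[3L]))
  for (c in seq_len(dim(img)[3L]))
    out[, , c] <- .resizeBilinearMat(img[, , c], h2, w2)
  out
}

# Squared distance of every pixel centre from (cx, cy), 0-based (x, y).
.dist2Grid <- function(h, w, cx, cy) {
  dy2 <- ((seq_len(h) - 1L) - cy)^2
  dx2 <- ((seq_len(w) - 1L) - cx)^2
  outer(dy2, dx2, "+")
}

.circleMask <- function(h, w, cx, cy, r) {
  .dist2Grid(h, w, cx, cy) <= r^2
}

.assertImage <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stop("expected a height x width x 3 RGB array", call. = FALSE)
  invisible(image)
}

.assertGray <- function(gray) {
  if (!is.matrix(gray))
    stop("expected a grayscale matrix", call. = FALSE)
  invisible(gray)
}

# Area of intersection of two circles with radii r1, r2 at centre distance d.
.circleOverlapArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt(pmax((-d + r1 + r2) * (d + r1 - r2) *
                        (d - r1 + r2) * (d + r1 + r2), 0))
  a1 + a2 - a3
}
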