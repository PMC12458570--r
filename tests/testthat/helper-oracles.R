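# Brute-force oracles shared across test files: explicit loops over pixels
# and boundary point pairs, no shared code with the implementation.

bruteConfusion <- function(p, q) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] && q[i, j]) tp <- tp + 1
    else if (p[i, j] && !q[i, j]) fp <- fp + 1
    else if (!p[i, j] && q[i, j]) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

bruteBoundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pts <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!m[i, j]) next
    isB <- FALSE
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > h || jj < 1 || jj > w || !m[ii, jj]) isB <- TRUE
    }
    if (isB) pts <- rbind(pts, c(j - 1, i - 1))
  }
  pts
}

bruteDirected <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (k in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[k, 1])^2 + (a[i, 2] - b[k, 2])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

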