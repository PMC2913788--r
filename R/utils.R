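# Internal raster helpers shared across modules. All work on plain numeric
# matrices indexed (row, col), 1-based, row-major like base R.

#' @noRd
shift_mat <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(ri) > 0L && length(rj) > 0L)
    out[ri, rj] <- m[ri - di, rj - dj]
  out
}

# Sliding-window sum over a (2*ri+1) x (2*rj+1) box, zero padded, via
# integral images. Exact (no FFT round-off), O(N).
#' @noRd
box_sum <- function(m, ri, rj = ri) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2 * ri + 1, nc + 2 * rj + 1)
  p[(ri + 2):(ri + 1 + nr), (rj + 2):(rj + 1 + nc)] <- m
  p <- apply(p, 2, cumsum)
  p <- t(apply(p, 1, cumsum))
  i1 <- (2 * ri + 2):(2 * ri + 1 + nr); i0 <- 1:nr
  j1 <- (2 * rj + 2):(2 * rj + 1 + nc); j0 <- 1:nc
  p[i1, j1] - p[i0, j1] - p[i1, j0] + p[i0, j0]
}

#' @noRd
box_count <- function(mask, ri, rj = ri) {
  box_sum(matrix(as.numeric(mask), nrow(mask)), ri, rj)
}

# Windowed mean/variance restricted to pixels where `w` (weights/indicator)
# is nonzero; population variance.
#' @noRd
box_stats <- function(m, ri, rj = ri, w = NULL) {
  if (is.null(w)) w <- matrix(1, nrow(m), ncol(m))
  n <- box_sum(w, ri, rj)
  s1 <- box_sum(m * w, ri, rj)
  s2 <- box_sum(m * m * w, ri, rj)
  mu <- ifelse(n > 0, s1 / n, 0)
  va <- ifelse(n > 0, pmax(0, s2 / n - mu^2), 0)
  list(n = n, mean = mu, var = va)
}

# Separable sliding maximum over a (2r+1)^2 box (shift-compare, exact).
#' @noRd
box_max <- function(m, r) {
  rowmax <- m
  for (d in seq_len(r)) {
    rowmax <- pmax(rowmax, shift_mat(m, d, 0, -Inf), shift_mat(m, -d, 0, -Inf))
  }
  out <- rowmax
  for (d in seq_len(r)) {
    out <- pmax(out, shift_mat(rowmax, 0, d, -Inf), shift_mat(rowmax, 0, -d, -Inf))
  }
  out
}

#' @noRd
box_min <- function(m, r) -box_max(-m, r)

# Integer pixel chain between two points (inclusive), dense enough to be
# 8-connected: sampled at unit steps along the segment.
#' @noRd
raster_segment <- function(a, b) {
  d <- sqrt(sum((b - a)^2))
  n <- max(1L, ceiling(d))
  t <- seq(0, 1, length.out = n + 1L)
  pts <- cbind(round(a[1] + t * (b[1] - a[1])), round(a[2] + t * (b[2] - a[2])))
  pts[!duplicated(pts), , drop = FALSE]
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Discrete 2D Gaussian on an odd window, normalised to sum 1.
#' @noRd
gaussian_kernel2d <- function(size, sigma) {
  half <- floor(size / 2)
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Correlation of `img` with kernel `k` (odd dims) via EBImage FFT
# convolution; boundary handled by `boundary` (0 or "replicate").
#' @noRd
correlate2d <- function(img, k, boundary = 0) {
  kf <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
  as.matrix(EBImage::filter2(img, kf, boundary = boundary))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
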