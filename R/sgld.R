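#' Spatial grey-level difference (co-occurrence) matrix
#'
#' The 256 x 256 joint probability that grey levels `k1` and `k2` occur at
#' the two ends of a fixed displacement vector, estimated over all pixel
#' pairs whose two endpoints both lie inside the FOV. Values are taken
#' modulo rounding to the 8-bit range \[0, 255\].
#'
#' @param img a [grey_image] with 8-bit grey levels.
#' @param displacement integer 2-vector `(d_row, d_col)` in pixels.
#' @return an `sgld_matrix`: list with the 256 x 256 probability matrix
#'   `P`, the `displacement` and the pair count `n_pairs`.
#' @examples
#' m <- compute_sgld(grey_image(matrix(7, 16, 16)), c(0, 1))
#' m$P[8, 8]  # constant image: all mass at (7, 7)
#' @export
compute_sgld <- function(img, displacement) {
  img <- as_grey_image(img)
  d <- as.integer(round(displacement))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  if (abs(d[1]) >= nr || abs(d[2]) >= nc)
    stop("displacement exceeds the image extent")
  g <- clamp(round(img$pixels), 0, 255)
  # source window such that both p and p + d are in frame
  si <- max(1, 1 - d[1]):min(nr, nr - d[1])
  sj <- max(1, 1 - d[2]):min(nc, nc - d[2])
  k1 <- g[si, sj, drop = FALSE]
  k2 <- g[si + d[1], sj + d[2], drop = FALSE]
  ok <- img$fov[si, sj, drop = FALSE] & img$fov[si + d[1], sj + d[2], drop = FALSE]
  idx <- k1[ok] * 256 + k2[ok] + 1
  n <- length(idx)
  if (n == 0L) stop("no valid pixel pairs for this displacement")
  P <- matrix(tabulate(idx, nbins = 256L * 256L) / n, 256L, 256L, byrow = TRUE)
  structure(list(P = P, displacement = d, n_pairs = n), class = "sgld_matrix")
}

#' @export
print.sgld_matrix <- function(x, ...) {
  cat(sprintf("<sgld_matrix> displacement (%d, %d), %d pairs\n",
              x$displacement[1], x$displacement[2], x$n_pairs))
  invisible(x)
}

#' Scalar texture features of an SGLD matrix
#'
#' Summaries of the joint grey-level distribution: energy (sum of squared
#' probabilities), marginal mean and variance, correlation between the two
#' ends, Shannon entropy (natural log, with `0 log 0 = 0`) and the mean
#' absolute grey-level difference across the displacement.
#'
#' @param m an [compute_sgld] result.
#' @return named list: `mean`, `energy`, `correlation`, `variance`,
#'   `entropy`, `mean_gl_difference`.
#' @export
sgld_features <- function(m) {
  stopifnot(inherits(m, "sgld_matrix"))
  P <- m$P
  gl <- 0:255
  p1 <- rowSums(P); p2 <- colSums(P)
  mu1 <- sum(gl * p1); mu2 <- sum(gl * p2)
  v1 <- sum((gl - mu1)^2 * p1); v2 <- sum((gl - mu2)^2 * p2)
  cov12 <- sum(outer(gl - mu1, gl - mu2) * P)
  corr <- if (v1 > 0 && v2 > 0) cov12 / sqrt(v1 * v2) else NA_real_
  nz <- P > 0
  list(mean = (mu1 + mu2) / 2,
       energy = sum(P^2),
       correlation = corr,
       variance = (v1 + v2) / 2,
       entropy = -sum(P[nz] * log(P[nz])),
       mean_gl_difference = sum(abs(outer(gl, gl, "-")) * P))
}

#' Estimate dominant vessel widths from SGLD symmetry
#'
#' Scores each candidate displacement magnitude (along the normal to the
#' locally dominant orientation) by how strongly similar grey levels
#' co-occur across it within the region of interest: at a displacement
#' equal to the vessel width, one wall is mapped onto the opposite wall and
#' like tissue is re-encountered, concentrating the SGLD near its diagonal.
#' The score is the near-diagonal co-occurrence probability weighted by the
#' fraction of region pixels whose displaced partner also falls in the
#' region. Scored magnitudes that are local maxima above `score_thr` are
#' returned, optionally snapped to a configured candidate width set.
#'
#' @param img a [grey_image].
#' @param region logical matrix of pixels to score (e.g. wall candidates).
#' @param d_magnitudes displacement magnitudes tried, px.
#' @param orientation dominant along-vessel angle in radians, or `NULL` to
#'   estimate it as the circular mean of the gradient orientation over the
#'   region.
#' @param candidate_set widths the estimates are snapped to; `NULL`
#'   disables snapping. The default follows the coarse three-octave grid
#'   16/32/64; pass `5:50` for the dense pairing grid.
#' @param diag_delta near-diagonal band half-width in grey levels.
#' @param score_thr minimum absolute score for a candidate.
#' @param top_k maximal number of candidates returned.
#' @return data.frame with columns `width` (measured magnitude), `score`,
#'   `snapped` (candidate-set width or `NA`), `low_confidence` (snap moved
#'   the estimate by more than 25%).
#' @export
estimate_dominant_widths <- function(img, region,
                                     d_magnitudes = 2:30,
                                     orientation = NULL,
                                     candidate_set = c(16, 32, 64),
                                     diag_delta = 16,
                                     score_thr = 0.02,
                                     top_k = 3) {
  img <- as_grey_image(img)
  region <- region & img$fov
  if (!any(region)) stop("empty region")
  if (is.null(orientation)) {
    f <- compute_gradient(img)
    th <- f$theta[region & !f$undefined]
    orientation <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2
  }
  # normal to the vessel axis = gradient direction
  nvec <- c(sin(orientation + pi / 2), cos(orientation + pi / 2))
  g <- clamp(round(img$pixels), 0, 255)
  nr <- nrow(g); nc <- ncol(g)
  n_region <- sum(region)

  seen <- character(0)
  score <- rep(NA_real_, length(d_magnitudes))
  for (k in seq_along(d_magnitudes)) {
    d <- round(d_magnitudes[k] * nvec)
    key <- paste(d, collapse = ",")
    if (key %in% seen || all(d == 0)) next
    seen <- c(seen, key)
    si <- max(1, 1 - d[1]):min(nr, nr - d[1])
    sj <- max(1, 1 - d[2]):min(nc, nc - d[2])
    if (length(si) == 0L || length(sj) == 0L) next
    both <- region[si, sj, drop = FALSE] &
            region[si + d[1], sj + d[2], drop = FALSE]
    npairs <- sum(both)
    if (npairs == 0L) { score[k] <- 0; next }
    dd <- abs(g[si, sj, drop = FALSE][both] -
              g[si + d[1], sj + d[2], drop = FALSE][both])
    diag_frac <- mean(dd <= diag_delta)
    coverage <- npairs / n_region
    score[k] <- diag_frac * coverage
  }

  d <- d_magnitudes[!is.na(score)]
  s <- score[!is.na(score)]
  if (length(d) == 0L)
    return(data.frame(width = numeric(0), score = numeric(0),
                      snapped = numeric(0), low_confidence = logical(0)))
  # local maxima above the absolute threshold
  is_peak <- vapply(seq_along(s), function(i) {
    left <- if (i > 1) s[i - 1] else -Inf
    right <- if (i < length(s)) s[i + 1] else -Inf
    s[i] >= left && s[i] >= right && s[i] >= score_thr
  }, logical(1))
  d <- d[is_peak]; s <- s[is_peak]
  if (length(d) == 0L)
    return(data.frame(width = numeric(0), score = numeric(0),
                      snapped = numeric(0), low_confidence = logical(0)))
  ord <- order(s, decreasing = TRUE)
  keep <- ord[seq_len(min(top_k, length(ord)))]
  width <- d[keep]; sc <- s[keep]
  if (is.null(candidate_set)) {
    snapped <- rep(NA_real_, length(width)); lowc <- rep(FALSE, length(width))
  } else {
    snapped <- vapply(width, function(w) candidate_set[which.min(abs(candidate_set - w))],
                      numeric(1))
    lowc <- abs(snapped - width) / pmax(width, 1) > 0.25
  }
  data.frame(width = width, score = sc, snapped = snapped,
             low_confidence = lowc)
}
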