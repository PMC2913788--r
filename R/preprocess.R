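#' Gaussian smoothing
#'
#' Convolves the image with a normalised discrete Gaussian. `kernel_size`
#' names the truncation window (8 up to 32 px); the Gaussian sigma is tied
#' to it as `kernel_size / 4`. Even sizes are widened to the next odd
#' window so the kernel has a well-defined centre. Borders are handled by
#' edge replication; the FOV mask is passed through unchanged and values
#' are clipped to \[0, 255\] only at output.
#'
#' @param img a [grey_image] (or numeric matrix).
#' @param kernel_size truncation window in px, in \[8, 32\].
#' @param sigma Gaussian sigma; default `kernel_size / 4`.
#' @return the smoothed [grey_image].
#' @export
smooth_image <- function(img, kernel_size = 8, sigma = kernel_size / 4) {
  img <- as_grey_image(img)
  if (kernel_size < 8 || kernel_size > 32)
    stop("kernel_size must lie in [8, 32]")
  size <- 2L * floor(kernel_size / 2) + 1L
  if (size > min(dim(img$pixels)))
    stop("smoothing kernel larger than image")
  k <- gaussian_kernel2d(size, sigma)
  out <- correlate2d(img$pixels, k, boundary = "replicate")
  grey_image(clamp(out, 0, 255), img$fov)
}

#' Illumination correction
#'
#' Compensates for smooth illumination non-uniformity: a large-scale
#' background estimate (Gaussian smoothing with a window at least four
#' times the widest expected vessel) is subtracted, the result is
#' re-centred on the original FOV-mean grey level, and random bright
#' peaks beyond three global standard deviations above the mean are
#' clipped. Only the bright side is clipped: vessels are the dark tail of
#' the distribution and must survive the correction.
#'
#' @param img a [grey_image].
#' @param background_window background-estimation window in px; default
#'   4 x 50 (four times the widest vessel accepted by wall pairing).
#' @param peak_sigmas clipping range in global standard deviations.
#' @return the corrected [grey_image].
#' @export
correct_illumination <- function(img, background_window = 200, peak_sigmas = 3) {
  img <- as_grey_image(img)
  size <- 2L * floor(background_window / 2) + 1L
  size <- min(size, 2L * floor((min(dim(img$pixels)) - 1L) / 2) + 1L)
  k <- gaussian_kernel2d(size, size / 4)
  bg <- correlate2d(img$pixels, k, boundary = "replicate")
  m0 <- mean(img$pixels[img$fov])
  out <- img$pixels - bg + m0
  mu <- mean(out[img$fov]); sd0 <- stats::sd(out[img$fov])
  if (is.finite(sd0) && sd0 > 0)
    out <- pmin(out, mu + peak_sigmas * sd0)
  grey_image(clamp(out, 0, 255), img$fov)
}

#' Set the field of view to the inscribed ellipse
#'
#' Fundus photographs carry retina only inside a roughly elliptical disc;
#' all downstream statistics are restricted to this region. A user-supplied
#' mask is passed through unchanged.
#'
#' @param img a [grey_image].
#' @param mask optional logical matrix overriding the inscribed ellipse.
#' @return the [grey_image] with its `fov` replaced.
#' @export
fov_ellipse_mask <- function(img, mask = NULL) {
  img <- as_grey_image(img)
  if (is.null(mask)) {
    mask <- ellipse_mask(nrow(img$pixels), ncol(img$pixels))
  } else {
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
    if (!all(dim(mask) == dim(img$pixels)))
      stop("mask must match the image shape")
  }
  grey_image(img$pixels, mask)
}
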