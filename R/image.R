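#' Grey-level image with field-of-view mask
#'
#' The universal pixel container used throughout the package: an 8-bit style
#' grey-level raster (values nominally in \[0, 255\], stored as doubles) plus
#' a logical field-of-view (FOV) mask of the same shape. All statistics
#' computed downstream (gradient normalisation, SGLD pair counting, local
#' thresholds, confusion counts) are restricted to the FOV.
#'
#' @param pixels numeric matrix of grey levels; finite values required.
#' @param fov_mask optional logical matrix, same shape; default all `TRUE`.
#' @return an object of class `grey_image`: a list with elements `pixels`
#'   and `fov`.
#' @examples
#' img <- grey_image(matrix(128, 32, 32))
#' dim(img$pixels)
#' @export
grey_image <- function(pixels, fov_mask = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (length(pixels) == 0L) stop("zero-area image")
  if (any(!is.finite(pixels))) stop("pixels must be finite")
  if (is.null(fov_mask)) {
    fov_mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  } else {
    fov_mask <- matrix(as.logical(fov_mask), nrow(fov_mask), ncol(fov_mask))
    if (!all(dim(fov_mask) == dim(pixels)))
      stop("fov_mask must match the image shape")
  }
  structure(list(pixels = pixels, fov = fov_mask), class = "grey_image")
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d, GL range [%.1f, %.1f], FOV %.1f%%\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels),
              100 * mean(x$fov)))
  invisible(x)
}

#' @noRd
as_grey_image <- function(x) {
  if (inherits(x, "grey_image")) return(x)
  grey_image(x)
}

#' Read an 8-bit image as a grey_image
#'
#' Reads PNG and TIFF through the \pkg{png} / \pkg{tiff} packages and the
#' plain ASCII/binary PNM family (PGM/PPM) directly. RGB inputs are reduced
#' to the green channel, the standard practice for fundus photographs where
#' vessel/background contrast is strongest in green.
#'
#' @param path file path (.png, .tif/.tiff, .pgm, .ppm).
#' @param channel channel used for colour inputs, `"green"` (default),
#'   `"red"`, `"blue"` or `"luminance"`.
#' @return a [grey_image] with values in \[0, 255\] and an all-TRUE FOV.
#' @export
read_image <- function(path, channel = c("green", "red", "blue", "luminance")) {
  channel <- match.arg(channel)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path) * 255
    },
    pgm = ,
    ppm = read_pnm(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(arr)) == 3L) {
    g <- switch(channel,
      red = arr[, , 1], green = arr[, , 2], blue = arr[, , 3],
      luminance = 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  } else g <- arr
  grey_image(g)
}

# Minimal PNM (P2/P5 grey, P3/P6 colour) reader; no R package on hand
# exposes this format.
#' @noRd
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PNM header")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) {
        buf <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) break
          buf <- paste0(buf, ch)
        }
        return(buf)
      }
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("unsupported PNM type: ", magic)
  w <- as.integer(tok()); h <- as.integer(tok()); mx <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  }
  vals <- vals * (255 / mx)
  if (nch == 1L) {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3L))
    for (c3 in 1:3) a[, , c3] <- matrix(vals[seq(c3, n, by = 3L)], h, w, byrow = TRUE)
    a
  }
}

#' Write a binary mask or a grey image as PNG
#'
#' Masks are written as 0/255 8-bit PNG; grey images are clipped to
#' \[0, 255\] and scaled to the PNG unit range.
#'
#' @param x logical/binary matrix (for `write_mask_png`) or numeric matrix /
#'   [grey_image] (for `write_grey_png`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(x, path) {
  m <- matrix(as.numeric(x != 0), nrow(x), ncol(x))
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
write_grey_png <- function(x, path) {
  if (inherits(x, "grey_image")) x <- x$pixels
  png::writePNG(clamp(x, 0, 255) / 255, path)
  invisible(path)
}
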