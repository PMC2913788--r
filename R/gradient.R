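#' Gradient field and local orientation frame
#'
#' Central-difference gradient of the (smoothed) grey-level surface inside
#' the FOV, with the per-pixel local frame used throughout wall detection:
#' the unit gradient direction (the across-vessel axis, pointing from dark
#' lumen towards bright background at a wall) and the orientation unit
#' vector, its +90 degree rotation (the along-vessel axis). Global gradient
#' statistics — the FOV mean gradient magnitude and its standard deviation —
#' normalise the gradient-strength measure downstream.
#'
#' @param img a [grey_image], normally already smoothed.
#' @return a `gradient_field`: list with matrices `gi`, `gj` (row/col
#'   derivatives), `mag`, `ui`, `uj` (unit gradient direction), `oi`, `oj`
#'   (orientation, perpendicular to the gradient), `theta` (orientation
#'   angle in \[0, pi)), plus scalars `global_mean_mag`, `global_std` and
#'   the image FOV. Pixels with zero magnitude have undefined direction
#'   (flagged by the logical matrix `undefined`).
#' @export
compute_gradient <- function(img) {
  img <- as_grey_image(img)
  p <- img$pixels
  nr <- nrow(p); nc <- ncol(p)
  gi <- (shift_mat(p, -1, 0, 0) - shift_mat(p, 1, 0, 0)) / 2   # d/d(row)
  gj <- (shift_mat(p, 0, -1, 0) - shift_mat(p, 0, 1, 0)) / 2   # d/d(col)
  # one-sided differences on the frame border
  gi[1, ] <- p[2, ] - p[1, ]; gi[nr, ] <- p[nr, ] - p[nr - 1, ]
  gj[, 1] <- p[, 2] - p[, 1]; gj[, nc] <- p[, nc] - p[, nc - 1]
  # the gradient is only defined where the whole difference stencil lies
  # inside the FOV; otherwise the FOV rim itself would masquerade as the
  # strongest edge in the image
  interior <- img$fov &
    shift_mat(img$fov + 0, 1, 0, 0) > 0 & shift_mat(img$fov + 0, -1, 0, 0) > 0 &
    shift_mat(img$fov + 0, 0, 1, 0) > 0 & shift_mat(img$fov + 0, 0, -1, 0) > 0
  gi[!interior] <- 0; gj[!interior] <- 0
  mag <- sqrt(gi^2 + gj^2)
  undefined <- mag == 0
  safe <- ifelse(undefined, 1, mag)
  ui <- gi / safe; uj <- gj / safe
  ui[undefined] <- 0; uj[undefined] <- 0
  # orientation = gradient rotated +90 degrees: (i,j) -> (-j, i)
  oi <- -uj; oj <- ui
  theta <- atan2(oi, oj) %% pi
  fovmag <- mag[img$fov]
  structure(list(gi = gi, gj = gj, mag = mag,
                 ui = ui, uj = uj, oi = oi, oj = oj, theta = theta,
                 undefined = undefined,
                 global_mean_mag = mean(fovmag),
                 global_std = sqrt(mean((fovmag - mean(fovmag))^2)),
                 fov = img$fov),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %d x %d, mean |grad| %.3f, sd %.3f\n",
              nrow(x$mag), ncol(x$mag), x$global_mean_mag, x$global_std))
  invisible(x)
}

#' Relative gradient-strength map
#'
#' The Gaussian gradient-strength measure
#' `s = A * exp(-||grad||^2 / (2 * sigma^2))` with `sigma` the global
#' (FOV-wide) standard deviation of the gradient magnitude and `A` the
#' maximum gradient magnitude over a square neighbourhood of the pixel, so
#' the measure is locally sensitive. As written the exponent uses the raw
#' squared magnitude, which peaks at flat pixels; `deviation_form = TRUE`
#' switches the exponent to the squared deviation from the global mean
#' magnitude, which peaks at typical-gradient pixels. Wall-candidate
#' selection therefore uses the magnitude jointly with this map rather
#' than the map alone.
#'
#' @param field a [compute_gradient] result.
#' @param neighborhood_radius half-width of the window defining `A`
#'   (window side `2*radius+1`, default 4 -> 9 px).
#' @param deviation_form use `(||grad|| - mean)^2` in the exponent.
#' @return numeric matrix of strengths, in `[0, A]` pixel-wise.
#' @export
gradient_strength <- function(field, neighborhood_radius = 4,
                              deviation_form = FALSE) {
  stopifnot(inherits(field, "gradient_field"))
  A <- box_max(field$mag, neighborhood_radius)
  s2 <- field$global_std^2
  if (s2 == 0) {
    warning("constant gradient field: strength defined as A everywhere")
    return(A)
  }
  dev <- if (deviation_form) (field$mag - field$global_mean_mag)^2 else field$mag^2
  A * exp(-dev / (2 * s2))
}

#' Orientation scope map
#'
#' The scope of the local orientation at a pixel is the largest radius `r`
#' over which the gradient field stays homogeneous: the Gaussian
#' homogeneity score `exp(-sd_r^2 / sigma_ref^2)`, with `sd_r` the
#' standard deviation of the gradient magnitude over the `(2r+1)^2` window
#' and `sigma_ref` the global gradient SD, must stay at or above `thr` for
#' every radius up to `r`. The score is 1 on perfectly homogeneous
#' neighbourhoods and `exp(-1) ~ 0.37` where the local spread matches the
#' image-wide spread, so the 0.5 default separates coherent structure from
#' noise. Shrinking `thr` never shrinks the scope; `thr = 0` returns
#' `r_max` everywhere.
#'
#' @param field a [compute_gradient] result.
#' @param r_max largest radius searched, px.
#' @param thr homogeneity threshold in (0, 1\]; 0 disables the test.
#' @return integer matrix of scopes in `[0, r_max]`.
#' @export
orientation_scope <- function(field, r_max = 8, thr = 0.5) {
  stopifnot(inherits(field, "gradient_field"))
  s2 <- field$global_std^2
  scope <- matrix(0L, nrow(field$mag), ncol(field$mag))
  if (s2 == 0) return(scope + as.integer(r_max))
  alive <- matrix(TRUE, nrow(field$mag), ncol(field$mag))
  for (r in seq_len(r_max)) {
    st <- box_stats(field$mag, r)
    score <- exp(-st$var / s2)
    alive <- alive & (score >= thr)
    scope[alive] <- r
  }
  scope
}

#' Local homogeneity (block variance) maps
#'
#' Per-pixel variance over a square block (default 8 x 8) of three local
#' descriptors: gradient magnitude, orientation angle (circular variance of
#' the axial orientation) and the curvature proxy (magnitude of the spatial
#' derivative of the orientation angle along the vessel direction). These
#' are the homogeneity criteria that act as spatial filters on wall-pixel
#' candidates.
#'
#' @param field a [compute_gradient] result.
#' @param block block side in px (window is the centred odd window of
#'   comparable area, side `2*floor(block/2)+1`).
#' @return list of matrices `grad_var`, `orient_var` (in \[0,1\]) and
#'   `curv_var`.
#' @export
local_homogeneity <- function(field, block = 8) {
  stopifnot(inherits(field, "gradient_field"))
  r <- max(1L, floor(block / 2))
  grad_var <- box_stats(field$mag, r)$var

  # axial orientation: double the angle so theta and theta+pi coincide
  c2 <- cos(2 * field$theta); s2 <- sin(2 * field$theta)
  c2[field$undefined] <- 0; s2[field$undefined] <- 0
  w <- matrix(as.numeric(!field$undefined), nrow(c2))
  n <- box_sum(w, r)
  mc <- ifelse(n > 0, box_sum(c2 * w, r) / n, 0)
  ms <- ifelse(n > 0, box_sum(s2 * w, r) / n, 0)
  orient_var <- 1 - sqrt(pmin(mc^2 + ms^2, 1))
  orient_var[n == 0] <- 0

  # curvature proxy: |directional derivative of the (doubled) angle| along
  # the vessel axis; computed from the smooth unit-vector field
  d2t_i <- (shift_mat(s2 * w, -1, 0) - shift_mat(s2 * w, 1, 0)) / 2 * c2 -
           (shift_mat(c2 * w, -1, 0) - shift_mat(c2 * w, 1, 0)) / 2 * s2
  d2t_j <- (shift_mat(s2 * w, 0, -1) - shift_mat(s2 * w, 0, 1)) / 2 * c2 -
           (shift_mat(c2 * w, 0, -1) - shift_mat(c2 * w, 0, 1)) / 2 * s2
  curv <- abs(field$oi * d2t_i + field$oj * d2t_j) / 2
  curv_var <- box_stats(curv, r)$var

  list(grad_var = grad_var, orient_var = orient_var, curv_var = curv_var)
}
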