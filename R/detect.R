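# Local grey-level statistics used by the adaptive acceptance interval:
# the local mean is taken over a disk-like window whose radius follows the
# local GL standard deviation, floored at 3 px (the raw rule can yield a
# degenerate zero radius) and capped by the r_L parameter (at most 25 px).
# Radii are quantised to a small set so the means come from a handful of
# box filters.
#' @noRd
local_gl_stats <- function(img, r_L = 15) {
  p <- img$pixels
  st <- box_stats(p, 7, w = matrix(as.numeric(img$fov), nrow(p)))
  sd_map <- sqrt(st$var)
  radii <- c(3, 5, 8, 12, 17, 25)
  radii <- radii[radii <= max(3, min(25, r_L))]
  if (length(radii) == 0L) radii <- 3
  r_eff <- clamp(sd_map, 3, min(25, r_L))
  bucket <- vapply(as.vector(r_eff), function(r) which.min(abs(radii - r)),
                   integer(1))
  bucket <- matrix(bucket, nrow(p))
  mu <- matrix(0, nrow(p), ncol(p))
  fovw <- matrix(as.numeric(img$fov), nrow(p))
  for (b in seq_along(radii)) {
    sel <- bucket == b
    if (!any(sel)) next
    m <- box_stats(p, radii[b], w = fovw)$mean
    mu[sel] <- m[sel]
  }
  list(mu_L = mu, sd_L = sd_map, radius = matrix(radii[bucket], nrow(p)))
}

#' @noRd
gl_interval_ok <- function(gl, mu_L, lo = 0.5, hi = 2.5) {
  gl >= lo * mu_L & gl <= hi * mu_L
}

#' Guided coarse-to-fine vessel detection
#'
#' The mask-guided fine stage: the matched-filter bank is evaluated only at
#' the wall-pair midpoints (one convolution site per accepted wall-pixel
#' pair — interiors are inferred, not convolved). A pair is accepted when
#' its midpoint response exceeds `th_mfr` times the mean response over the
#' evaluated sites and the midpoint grey level falls in the adaptive local
#' interval `[0.5 mu_L, 2.5 mu_L]`; accepted pairs contribute their
#' connecting segment to the vessel map via [fill_interior] and their
#' midpoint to the centerline via [extract_centerline].
#'
#' @param img the preprocessed [grey_image].
#' @param wall a [build_wall_map] result.
#' @param bank an [make_bank] bank.
#' @param th_mfr response threshold as a fraction of the mean MFR.
#' @param r_L cap on the local-statistics radius, px.
#' @param max_bad_fraction tolerated fraction of failing pixels on a pair
#'   segment before the pair is dropped, see [fill_interior].
#' @param gap_max centerline gap bridging distance, px.
#' @return list with `vessel_map` (a `vessel_map`: `vp_mask`, `centerline`,
#'   `width_map`, `provenance = "guided"`) and `mfr` (the site-restricted
#'   `mfr_field`).
#' @export
guided_detect <- function(img, wall, bank, th_mfr = 0.5, r_L = 15,
                          max_bad_fraction = 0.25, gap_max = 5) {
  img <- as_grey_image(img)
  stopifnot(inherits(wall, "wall_pixel_map"))
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  empty_map <- structure(list(vp_mask = matrix(FALSE, nr, nc),
                              centerline = matrix(FALSE, nr, nc),
                              width_map = matrix(NA_real_, nr, nc),
                              provenance = "guided"),
                         class = "vessel_map")
  if (!any(wall$mask) || nrow(wall$pairs) == 0L) {
    warning("empty wall map: returning empty vessel map")
    mfr <- convolve_at(img, bank, matrix(integer(0), 0, 2))
    return(list(vessel_map = empty_map, mfr = mfr))
  }
  pr <- wall$pairs
  mid <- cbind(round((pr$ai + pr$bi) / 2), round((pr$aj + pr$bj) / 2))
  mfr <- convolve_at(img, bank, mid)
  # look responses back up per pair midpoint
  key <- function(m) paste(m[, 1], m[, 2])
  resp_at <- stats::setNames(mfr$response, key(mfr$sites))
  resp <- resp_at[key(mid)]
  thr <- th_mfr * mfr$mean_mfr

  st <- local_gl_stats(img, r_L = r_L)
  # the acceptance interval is anchored at the wall pixels (the accepted
  # VWP seeds): at a wall the local window straddles lumen and background,
  # so its mean separates the two — deep inside a wide lumen it would not
  mu_pair <- (st$mu_L[cbind(pr$ai, pr$aj)] + st$mu_L[cbind(pr$bi, pr$bj)]) / 2
  gl_mid <- img$pixels[mid]
  accept <- resp > thr & gl_interval_ok(gl_mid, mu_pair)
  accept[is.na(accept)] <- FALSE

  fill <- fill_interior(pr[accept, , drop = FALSE], img, st,
                        max_bad_fraction = max_bad_fraction,
                        gap_max = gap_max)
  cl <- extract_centerline_pairs(pr[accept, , drop = FALSE][fill$kept, ,
                                                            drop = FALSE],
                                 c(nr, nc), gap_max = gap_max)
  vm <- structure(list(vp_mask = fill$vp_mask | cl$centerline,
                       centerline = cl$centerline,
                       width_map = cl$width_map,
                       provenance = "guided"),
                  class = "vessel_map")
  list(vessel_map = vm, mfr = mfr)
}

#' Fill vessel interiors between paired wall pixels
#'
#' For each accepted pair the connecting segment is rasterised and its
#' pixels are tested against the adaptive grey-level interval (a lumen
#' pixel must not look like background). If the fraction of failing pixels
#' exceeds `max_bad_fraction` the pair is judged a false pairing (e.g. a
#' chord across background) and contributes no vessel pixels; otherwise
#' the whole segment is accepted.
#'
#' @param pairs pair data.frame (rows of [pair_wall_pixels] output).
#' @param img the preprocessed [grey_image].
#' @param gl_stats precomputed local GL statistics (internal); `NULL` to
#'   compute from `img`.
#' @param max_bad_fraction tolerated failing fraction per segment.
#' @param gap_max neighbouring accepted pairs whose midpoints lie within
#'   this distance have the cross-sections between them inferred by
#'   interpolated chords (the wall pixels there could not be paired
#'   directly, so interior pixels are interpolated from the well-paired
#'   neighbours).
#' @param endpoint_trim chord endpoints are pulled this many px towards the
#'   lumen — the wall ridge sits on the outer inflection of the profile, so
#'   untrimmed chords overshoot the vessel by a fraction of a pixel.
#' @return list: `vp_mask` (logical matrix of accepted vessel pixels),
#'   `kept` (logical per pair).
#' @export
fill_interior <- function(pairs, img, gl_stats = NULL,
                          max_bad_fraction = 0.25, gap_max = 5,
                          endpoint_trim = 1) {
  img <- as_grey_image(img)
  if (is.null(gl_stats)) gl_stats <- local_gl_stats(img)
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  vp <- matrix(FALSE, nr, nc)
  kept <- logical(nrow(pairs))
  if (nrow(pairs) == 0L) return(list(vp_mask = vp, kept = kept))

  trim <- function(a, b) {
    d <- b - a; len <- sqrt(sum(d^2))
    if (len <= 2 * endpoint_trim) return(list(a = a, b = b))
    u <- d / len
    list(a = a + endpoint_trim * u, b = b - endpoint_trim * u)
  }
  clamp_idx <- function(p) {
    cbind(pmin(pmax(round(p[1]), 1), nr), pmin(pmax(round(p[2]), 1), nc))
  }
  chord_ok <- function(a, b, a0 = a, b0 = b) {
    seg <- raster_segment(a, b)
    seg <- seg[seg[, 1] >= 1 & seg[, 1] <= nr &
               seg[, 2] >= 1 & seg[, 2] <= nc, , drop = FALSE]
    if (nrow(seg) == 0L) return(NULL)
    gl <- img$pixels[seg]
    # the reference level is the local mean at the wall seeds, where the
    # window straddles lumen and background; a chord through a true (dark)
    # lumen must consist of pixels inside the acceptance interval that are
    # darker than that reference, while a chord across background or
    # through a bright blob has about half (or most) of its pixels on the
    # bright side and is a false pairing
    mu <- (gl_stats$mu_L[clamp_idx(a0)] + gl_stats$mu_L[clamp_idx(b0)]) / 2
    bad <- !gl_interval_ok(gl, mu) | (gl - mu > -1)
    if (mean(bad) <= max_bad_fraction) seg else NULL
  }

  A <- cbind(pairs$ai, pairs$aj); B <- cbind(pairs$bi, pairs$bj)
  for (k in seq_len(nrow(pairs))) {
    tb <- trim(A[k, ], B[k, ])
    seg <- chord_ok(tb$a, tb$b, A[k, ], B[k, ])
    if (!is.null(seg)) { vp[seg] <- TRUE; kept[k] <- TRUE }
  }

  # interpolate the cross-sections between neighbouring accepted pairs
  ik <- which(kept)
  if (length(ik) >= 2L) {
    mid <- (A + B) / 2
    for (x in ik) {
      d2 <- (mid[ik, 1] - mid[x, 1])^2 + (mid[ik, 2] - mid[x, 2])^2
      nb <- ik[d2 > 0.5 & d2 <= gap_max^2]
      for (y in nb[nb > x]) {
        # align endpoints: wall a of pair x corresponds to whichever wall
        # of pair y is nearer to it
        ay <- A[y, ]; by <- B[y, ]
        if (sum((A[x, ] - ay)^2) > sum((A[x, ] - by)^2)) { tmp <- ay; ay <- by; by <- tmp }
        nstep <- ceiling(sqrt(sum((mid[y, ] - mid[x, ])^2)))
        for (s in seq_len(max(nstep - 1L, 1L)) / max(nstep, 2L)) {
          wa <- (1 - s) * A[x, ] + s * ay; wb <- (1 - s) * B[x, ] + s * by
          tb <- trim(wa, wb)
          seg <- chord_ok(tb$a, tb$b, wa, wb)
          if (!is.null(seg)) vp[seg] <- TRUE
        }
      }
    }
  }
  list(vp_mask = vp, kept = kept)
}

# Centerline from accepted pairs: midpoints carry the pair distance as the
# width estimate; gaps up to gap_max px are bridged by joining each
# midpoint to its two nearest neighbours with linearly interpolated width.
#' @noRd
extract_centerline_pairs <- function(pairs, dims, gap_max = 5) {
  cl <- matrix(FALSE, dims[1], dims[2])
  wmap <- matrix(NA_real_, dims[1], dims[2])
  if (nrow(pairs) == 0L) return(list(centerline = cl, width_map = wmap))
  mid <- cbind(round((pairs$ai + pairs$bi) / 2), round((pairs$aj + pairs$bj) / 2))
  w <- if ("width" %in% names(pairs)) pairs$width else pairs$distance
  dup <- duplicated(mid)
  mid <- mid[!dup, , drop = FALSE]; w <- w[!dup]
  cl[mid] <- TRUE
  wmap[mid] <- w
  n <- nrow(mid)
  if (n >= 2L) {
    for (k in seq_len(n)) {
      d2 <- (mid[, 1] - mid[k, 1])^2 + (mid[, 2] - mid[k, 2])^2
      d2[k] <- Inf
      nb <- order(d2)[1:min(2L, n - 1L)]
      for (b in nb) {
        if (d2[b] > gap_max^2 || d2[b] <= 2) next
        seg <- raster_segment(mid[k, ], mid[b, ])
        t <- seq(0, 1, length.out = nrow(seg))
        newpx <- is.na(wmap[seg])
        cl[seg] <- TRUE
        wmap[seg][newpx] <- ((1 - t) * w[k] + t * w[b])[newpx]
      }
    }
  }
  list(centerline = cl, width_map = wmap)
}

#' Extract the vessel centerline from a wall map
#'
#' The centerline pixel of each wall-pixel pair is the rounded midpoint and
#' its width estimate is the pair distance; gaps of at most `gap_max` px
#' between neighbouring midpoints are bridged by linear interpolation.
#'
#' @param wall a [build_wall_map] result.
#' @param gap_max bridging distance, px.
#' @return list: `centerline` (logical matrix), `width_map` (numeric
#'   matrix, `NA` off the centerline).
#' @export
extract_centerline <- function(wall, gap_max = 5) {
  stopifnot(inherits(wall, "wall_pixel_map"))
  extract_centerline_pairs(wall$pairs, dim(wall$mask), gap_max = gap_max)
}

#' Full-scan (MIP) vessel detection baseline
#'
#' Evaluates the bank at every FOV pixel via dense FFT correlation, takes
#' the per-pixel maximum response over the bank (maximum intensity
#' projection across orientations and scales) and labels a pixel as vessel
#' when its response exceeds `th_mfr` times the FOV-mean response and its
#' grey level falls in the adaptive local interval. `sites_evaluated`
#' equals the FOV pixel count.
#'
#' @inheritParams guided_detect
#' @return list with `vessel_map` (`provenance = "full_scan"`, empty
#'   centerline) and `mfr` (an `mfr_field` whose `response_map` matrix
#'   carries the dense responses).
#' @export
full_scan_detect <- function(img, bank, th_mfr = 0.75, r_L = 15) {
  img <- as_grey_image(img)
  dense <- mfr_dense(img, bank)
  fov <- img$fov
  mu <- mean(dense$response[fov])
  st <- local_gl_stats(img, r_L = r_L)
  vp <- fov & dense$response > th_mfr * mu &
    gl_interval_ok(img$pixels, st$mu_L)
  mfr <- structure(list(sites = which(fov, arr.ind = TRUE),
                        response = dense$response[fov],
                        best_angle = dense$best_angle[fov],
                        best_scale = dense$best_scale[fov],
                        sites_evaluated = sum(fov), sites_skipped = 0L,
                        mean_mfr = mu, dim = dim(fov),
                        response_map = dense$response),
                   class = "mfr_field")
  vm <- structure(list(vp_mask = vp,
                       centerline = matrix(FALSE, nrow(vp), ncol(vp)),
                       width_map = matrix(NA_real_, nrow(vp), ncol(vp)),
                       provenance = "full_scan"),
                  class = "vessel_map")
  list(vessel_map = vm, mfr = mfr)
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf("<vessel_map> provenance %s, %d vessel px, %d centerline px\n",
              x$provenance, sum(x$vp_mask), sum(x$centerline)))
  invisible(x)
}
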