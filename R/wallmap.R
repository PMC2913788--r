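#' Candidate vessel-wall pixels
#'
#' A pixel is a wall candidate iff its gradient magnitude (a) exceeds a
#' block-adaptive histogram threshold — the `percentile_thr` quantile of
#' magnitudes within its 32 x 32 tile — combined with a global floor at the
#' FOV mean gradient magnitude, and (b) is a 1-D local maximum of the
#' magnitude along the gradient direction (non-maximum suppression), so
#' candidate walls are thin ridges. With `percentile_thr = 0` all
#' suppressed-maxima pixels are accepted.
#'
#' @param field a [compute_gradient] result.
#' @param percentile_thr block-histogram quantile in \[0, 1).
#' @param block tile side for the adaptive threshold, px.
#' @param global_floor multiple of the FOV mean gradient magnitude every
#'   candidate must also exceed (ignored when `percentile_thr = 0`).
#' @return logical candidate mask.
#' @export
candidate_wall_pixels <- function(field, percentile_thr = 0.75, block = 32,
                                  global_floor = 1) {
  stopifnot(inherits(field, "gradient_field"))
  mag <- field$mag
  nr <- nrow(mag); nc <- ncol(mag)
  thr <- matrix(0, nr, nc)
  if (percentile_thr > 0) {
    ti <- ceiling(seq_len(nr) / block)
    tj <- ceiling(seq_len(nc) / block)
    for (a in unique(ti)) for (b in unique(tj)) {
      ri <- which(ti == a); rj <- which(tj == b)
      vals <- mag[ri, rj][field$fov[ri, rj]]
      q <- if (length(vals)) stats::quantile(vals, percentile_thr, names = FALSE) else Inf
      thr[ri, rj] <- max(q, global_floor * field$global_mean_mag)
    }
  }
  cand <- mag > thr & field$fov & !field$undefined

  # non-maximum suppression along the gradient direction (nearest pixel)
  di <- round(field$ui); dj <- round(field$uj)
  ii <- matrix(seq_len(nr), nr, nc); jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  fwd_i <- clamp(ii + di, 1, nr); fwd_j <- clamp(jj + dj, 1, nc)
  bck_i <- clamp(ii - di, 1, nr); bck_j <- clamp(jj - dj, 1, nc)
  m_fwd <- matrix(mag[cbind(as.vector(fwd_i), as.vector(fwd_j))], nr, nc)
  m_bck <- matrix(mag[cbind(as.vector(bck_i), as.vector(bck_j))], nr, nc)
  cand & mag >= m_fwd & mag > m_bck
}

#' Pair wall candidates across the vessel
#'
#' For each candidate, marches into the vessel (against its gradient, i.e.
#' from the bright side toward the dark lumen) and accepts the first
#' candidate encountered whose gradient is antiparallel (unit-direction dot
#' product at most `-cos(angle_tol)`), whose orientation agrees within
#' `angle_tol`, and whose distance lies in `width_range`. Matches are made
#' mutual by greedy nearest-distance assignment, so each pixel belongs to
#' at most one pair and `partner(partner(a)) = a`. The pair distance is the
#' wall-to-wall width estimate.
#'
#' @param candidates logical candidate mask.
#' @param field a [compute_gradient] result.
#' @param width_range accepted wall separation, px (default 5-50).
#' @param angle_tol alignment tolerance in degrees for both the
#'   antiparallel-gradient and the orientation test.
#' @return data.frame with one row per pair: `ai, aj, bi, bj` (pixel
#'   coordinates), `distance` (px), `angle` (pair axis, radians) and
#'   `quality` (alignment in \[0, 1\]).
#' @export
pair_wall_pixels <- function(candidates, field, width_range = c(5, 50),
                             angle_tol = 20) {
  stopifnot(inherits(field, "gradient_field"))
  idx <- which(candidates & !field$undefined, arr.ind = TRUE)
  empty <- data.frame(ai = integer(0), aj = integer(0), bi = integer(0),
                      bj = integer(0), distance = numeric(0),
                      angle = numeric(0), quality = numeric(0))
  if (nrow(idx) == 0L) return(empty)
  nr <- nrow(candidates); nc <- ncol(candidates)
  n_cand <- nrow(idx)
  ui <- field$ui[idx]; uj <- field$uj[idx]
  cos_tol <- cos(angle_tol * pi / 180)
  tmax <- ceiling(width_range[2])
  # the ray is sampled at unit steps; a thin (1 px) candidate ridge crossed
  # obliquely can fall between samples, so each sample also probes its
  # 8-neighbourhood (exact hit takes priority)
  probes <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))

  # one marching round over the still-unmatched candidates: each open pixel
  # walks against its gradient and keeps the first free candidate that
  # passes the antiparallel/orientation/width tests
  march_round <- function(free) {
    cand_id <- matrix(0L, nr, nc)
    cand_id[idx[free, , drop = FALSE]] <- which(free)
    found_b <- integer(n_cand); found_d <- rep(NA_real_, n_cand)
    found_q <- rep(NA_real_, n_cand)
    open <- free
    for (t in seq_len(tmax)) {
      act <- which(open)
      if (length(act) == 0L) break
      ci_ <- idx[act, 1] - t * ui[act]; cj_ <- idx[act, 2] - t * uj[act]
      b <- integer(length(act))
      for (pr in seq_len(nrow(probes))) {
        pi_ <- round(ci_) + probes[pr, 1]; pj_ <- round(cj_) + probes[pr, 2]
        inb <- pi_ >= 1 & pi_ <= nr & pj_ >= 1 & pj_ <= nc & b == 0L
        if (!any(inb)) next
        b[inb] <- cand_id[cbind(pi_[inb], pj_[inb])]
      }
      sel <- b > 0L & b != act
      if (!any(sel)) next
      a <- act[sel]; b <- b[sel]
      dist <- sqrt((idx[b, 1] - idx[a, 1])^2 + (idx[b, 2] - idx[a, 2])^2)
      dot <- ui[a] * ui[b] + uj[a] * uj[b]
      dth <- abs(field$theta[idx[a, , drop = FALSE]] -
                 field$theta[idx[b, , drop = FALSE]])
      dth <- pmin(dth, pi - dth)
      ok <- dot <= -cos_tol & dth <= angle_tol * pi / 180 &
        dist >= width_range[1] & dist <= width_range[2]
      a <- a[ok]; b <- b[ok]; dist <- dist[ok]; dot <- dot[ok]
      new <- is.na(found_d[a]) & !duplicated(a)
      found_b[a[new]] <- b[new]
      found_d[a[new]] <- dist[new]
      found_q[a[new]] <- pmin(1, -dot[new])
      open[a] <- FALSE
    }
    list(b = found_b, d = found_d, q = found_q)
  }

  # mutual 1:1 assignment, nearest pair first; conflicts (a partner already
  # claimed) cascade, so unmatched pixels get further rounds against the
  # remaining free candidates
  taken <- rep(FALSE, n_cand)
  pa <- integer(0); pb <- integer(0); pq <- numeric(0)
  for (round in 1:3) {
    m <- march_round(!taken)
    a <- which(!is.na(m$d) & !taken)
    a <- a[!taken[m$b[a]]]
    if (length(a) == 0L) break
    ord <- a[order(m$d[a])]
    added <- FALSE
    for (k in ord) {
      bk <- m$b[k]
      if (!taken[k] && !taken[bk]) {
        pa <- c(pa, k); pb <- c(pb, bk); pq <- c(pq, m$q[k])
        taken[k] <- TRUE; taken[bk] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  if (length(pa) == 0L) return(empty)
  dvec_i <- idx[pb, 1] - idx[pa, 1]; dvec_j <- idx[pb, 2] - idx[pa, 2]
  data.frame(ai = idx[pa, 1], aj = idx[pa, 2],
             bi = idx[pb, 1], bj = idx[pb, 2],
             distance = sqrt(dvec_i^2 + dvec_j^2),
             angle = atan2(dvec_i, dvec_j) %% pi,
             quality = pq)
}

#' Gaussian similarity inclusion of wall candidates
#'
#' Each paired candidate is graded against its accepted neighbours within
#' `radius` px on four features — gradient magnitude, gradient orientation,
#' grey level and local contrast (GL range over the 8 x 8 block). Per
#' feature the similarity is `exp(-(x - mu)^2 / (2 sigma^2))` with `mu`,
#' `sigma` the local neighbour statistics; the combined inclusion
#' probability is the product of the four factors, and a pixel is accepted
#' iff every feature deviates by at most two local standard deviations.
#' Pixels with fewer than `min_neighbors` accepted neighbours are deferred
#' (kept, with `NA` probability). A zero local sigma with a non-zero
#' deviation rejects the pixel with a degenerate-stats flag.
#'
#' @param img the (smoothed) [grey_image], source of the GL feature.
#' @param field a [compute_gradient] result.
#' @param mask logical matrix of paired candidate pixels.
#' @param radius neighbourhood radius for the local statistics, px.
#' @param min_neighbors minimum accepted neighbours required to grade.
#' @param n_sigma acceptance gate in standard deviations.
#' @return list: `accept` (logical matrix), `prob` (numeric matrix, `NA`
#'   where deferred/outside), `status` (factor matrix codes: 0 outside,
#'   1 accepted, 2 rejected, 3 deferred, 4 degenerate).
#' @export
gaussian_inclusion <- function(img, field, mask, radius = 15,
                               min_neighbors = 5, n_sigma = 2) {
  img <- as_grey_image(img)
  stopifnot(inherits(field, "gradient_field"))
  w <- matrix(as.numeric(mask), nrow(mask))
  nr <- nrow(mask); nc <- ncol(mask)

  gl <- img$pixels
  contrast <- box_max(gl, 4) - box_min(gl, 4)
  feats <- list(field$mag, gl, contrast)

  n <- box_sum(w, radius) - w  # exclude self
  prob <- matrix(1, nr, nc)
  accept <- mask
  status <- matrix(0L, nr, nc)
  status[mask] <- 1L
  deferred <- mask & n < min_neighbors
  status[deferred] <- 3L

  gate <- function(dev, sig) {
    # per-feature gate and Gaussian factor at graded pixels
    degen <- sig == 0 & dev > 1e-9
    factor <- ifelse(sig > 0, exp(-dev^2 / (2 * sig^2)), ifelse(degen, 0, 1))
    pass <- (dev <= n_sigma * sig) & !degen
    list(factor = factor, pass = pass, degen = degen)
  }

  graded <- mask & !deferred
  for (f in feats) {
    s1 <- box_sum(f * w, radius) - f * w
    s2 <- box_sum(f * f * w, radius) - f * f * w
    mu <- ifelse(n > 0, s1 / n, 0)
    sig <- sqrt(pmax(0, ifelse(n > 0, s2 / n - mu^2, 0)))
    g <- gate(abs(f - mu), sig)
    prob <- prob * g$factor
    accept <- accept & (!graded | g$pass)
    status[graded & g$degen] <- 4L
  }

  # orientation: circular statistics on the doubled angle
  c2 <- cos(2 * field$theta) * w; s2a <- sin(2 * field$theta) * w
  mc <- box_sum(c2, radius) - c2; msn <- box_sum(s2a, radius) - s2a
  rbar <- ifelse(n > 0, sqrt(mc^2 + msn^2) / n, 0)
  mu_th <- atan2(msn, mc) / 2
  dev_th <- abs(field$theta - mu_th) %% pi
  dev_th <- pmin(dev_th, pi - dev_th)
  sig_th <- sqrt(pmax(0, -2 * log(pmax(rbar, 1e-12)))) / 2
  g <- gate(dev_th, sig_th)
  prob <- prob * g$factor
  accept <- accept & (!graded | g$pass)
  status[graded & g$degen] <- 4L

  status[graded & !accept & status != 4L] <- 2L
  accept[deferred] <- TRUE
  prob[!graded] <- NA_real_
  prob[!mask] <- NA_real_
  list(accept = accept, prob = prob, status = status)
}

#' Remove sparse pixels from a binary mask
#'
#' Two cleanup modes for the vessel-wall map. `region_growing`: 4-connected
#' components are (optionally) grown by up to `max_steps` constrained
#' dilation steps within a support mask so nearby fragments merge, and any
#' component that recruited fewer than `min_size` original pixels is set to
#' background. `hough`: per 64 x 64 window, only pixels voting for a line
#' accumulator peak with at least `min_votes` votes are kept; when a local
#' orientation map is supplied the swept angle range is limited to the
#' window's dominant orientation +/- 15 degrees, otherwise the whole half
#' circle is swept. Output is always a subset of the input mask.
#'
#' @param mask logical matrix.
#' @param mode `"region_growing"` (default) or `"hough"`.
#' @param min_size minimum surviving component size, px (typical 10-15).
#' @param support optional logical matrix the growth is confined to.
#' @param max_steps dilation steps for the constrained growth.
#' @param orientation optional matrix of local orientations (radians) for
#'   hough mode; `NULL` sweeps all angles.
#' @param window hough window side, px.
#' @param min_votes hough peak threshold, px on a line.
#' @return pruned logical matrix.
#' @export
prune_sparse <- function(mask, mode = c("region_growing", "hough"),
                         min_size = 10, support = NULL, max_steps = 10,
                         orientation = NULL, window = 64, min_votes = 20) {
  mode <- match.arg(mode)
  if (!any(mask)) return(mask & FALSE)
  if (mode == "region_growing") {
    grown <- mask
    if (!is.null(support) && max_steps > 0) {
      cross <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
      # growth region: support padded by 1 px, so thin diagonal ridges
      # (8-connected but not 4-connected) can be traversed
      allowed <- as.matrix(EBImage::dilate((support | mask) + 0,
                                           matrix(1, 3, 3))) > 0
      for (s in seq_len(max_steps)) {
        nxt <- (as.matrix(EBImage::dilate(grown + 0, cross)) > 0) & allowed
        if (identical(nxt, grown)) break
        grown <- nxt
      }
    }
    lab <- label4(grown)
    sizes <- tabulate(lab[mask])          # original pixels recruited
    keep_lab <- which(sizes >= min_size)
    out <- mask & matrix(lab %in% keep_lab, nrow(mask))
    return(out)
  }
  # hough mode
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  for (i0 in seq(1, nr, by = window)) for (j0 in seq(1, nc, by = window)) {
    ri <- i0:min(i0 + window - 1, nr); rj <- j0:min(j0 + window - 1, nc)
    sub <- mask[ri, rj, drop = FALSE]
    pts <- which(sub, arr.ind = TRUE)
    if (nrow(pts) == 0L) next
    if (is.null(orientation)) {
      # no orientation prior: sweep the whole half circle
      angles <- seq(0, pi - 1e-9, by = 3 * pi / 180)
    } else {
      th <- orientation[ri, rj][sub]
      th0 <- atan2(mean(sin(2 * th)), mean(cos(2 * th))) / 2
      angles <- th0 + seq(-15, 15, by = 3) * pi / 180
    }
    keep <- rep(FALSE, nrow(pts))
    for (th in angles) {
      # lines along direction (sin th, cos th): the across-line offset
      # rho = i cos(th) - j sin(th) is constant on each line
      rho <- round(pts[, 1] * cos(th) - pts[, 2] * sin(th))
      votes <- table(rho)
      peaks <- as.integer(names(votes)[votes >= min_votes])
      if (length(peaks)) keep <- keep | (rho %in% peaks)
    }
    sub2 <- sub & FALSE
    sub2[pts[keep, , drop = FALSE]] <- TRUE
    out[ri, rj] <- out[ri, rj] | sub2
  }
  out & mask
}

# 4-connected component labelling (EBImage::bwlabel uses 4-connectivity).
#' @noRd
label4 <- function(mask) {
  as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
}

# Local-consensus width: a single pair distance carries the localisation
# jitter of two noisy wall ridges, so each pair's width estimate is the
# median distance over the neighbouring pairs that run in the same
# direction (midpoints within `radius` px, axis within `angle_tol`).
# Homogeneity is thus forced on the width estimates the way it is on the
# wall features themselves.
#' @noRd
consensus_widths <- function(pairs, radius = 7, angle_tol = 30) {
  if (nrow(pairs) == 0L) {
    pairs$width <- numeric(0)
    return(pairs)
  }
  mi <- (pairs$ai + pairs$bi) / 2
  mj <- (pairs$aj + pairs$bj) / 2
  tol <- angle_tol * pi / 180
  width <- pairs$distance
  for (k in seq_len(nrow(pairs))) {
    d2 <- (mi - mi[k])^2 + (mj - mj[k])^2
    dth <- abs(pairs$angle - pairs$angle[k])
    dth <- pmin(dth, pi - dth)
    nb <- d2 <= radius^2 & dth <= tol
    width[k] <- stats::median(pairs$distance[nb])
  }
  pairs$width <- width
  pairs
}

#' Build the vessel-wall-pixel map
#'
#' The coarse stage end to end: gradient-based candidate selection,
#' antiparallel pairing within the accepted width range, Gaussian
#' similarity inclusion, and sparse-pixel pruning. The surviving paired
#' pixels form the binary VWP mask that guides all matched-filter work.
#'
#' @param img the preprocessed [grey_image].
#' @param field a [compute_gradient] result (computed from `img` if `NULL`).
#' @param width_range accepted wall separation, px.
#' @param percentile_thr block-histogram quantile for candidates.
#' @param angle_tol pairing alignment tolerance, degrees.
#' @param inclusion_radius neighbourhood radius of the similarity gate, px.
#' @param min_size pruning component-size threshold, px.
#' @param prune_mode `"region_growing"` or `"hough"`.
#' @return a `wall_pixel_map`: list with `mask` (logical), `pairs`
#'   (data.frame as in [pair_wall_pixels], restricted to surviving pairs),
#'   `inclusion_prob` (numeric matrix), `candidates` (pre-pairing mask) and
#'   `field`.
#' @export
build_wall_map <- function(img, field = NULL, width_range = c(5, 50),
                           percentile_thr = 0.75, angle_tol = 20,
                           inclusion_radius = 15, min_size = 10,
                           prune_mode = "region_growing") {
  img <- as_grey_image(img)
  if (is.null(field)) field <- compute_gradient(img)
  cand <- candidate_wall_pixels(field, percentile_thr = percentile_thr)
  pairs <- pair_wall_pixels(cand, field, width_range = width_range,
                            angle_tol = angle_tol)
  mask <- matrix(FALSE, nrow(cand), ncol(cand))
  if (nrow(pairs) > 0) {
    mask[cbind(pairs$ai, pairs$aj)] <- TRUE
    mask[cbind(pairs$bi, pairs$bj)] <- TRUE
  }
  inc <- gaussian_inclusion(img, field, mask, radius = inclusion_radius)
  mask <- inc$accept
  mask <- prune_sparse(mask, mode = prune_mode, min_size = min_size,
                       support = cand, max_steps = 10)
  if (nrow(pairs) > 0) {
    alive <- mask[cbind(pairs$ai, pairs$aj)] & mask[cbind(pairs$bi, pairs$bj)]
    pairs <- pairs[alive, , drop = FALSE]
  }
  pairs <- consensus_widths(pairs)
  structure(list(mask = mask, pairs = pairs, inclusion_prob = inc$prob,
                 candidates = cand, field = field),
            class = "wall_pixel_map")
}

#' @export
print.wall_pixel_map <- function(x, ...) {
  cat(sprintf("<wall_pixel_map> %d wall pixels, %d pairs, mask fraction %.4f of FOV\n",
              sum(x$mask), nrow(x$pairs), sum(x$mask) / sum(x$field$fov)))
  invisible(x)
}
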