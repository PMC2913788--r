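#' Pixel-wise confusion counts against ground truth
#'
#' Counts true/false positives/negatives over FOV pixels only and derives
#' sensitivity `SE = TP / (TP + FN)` and specificity `SP = TN / (FP + TN)`.
#' With `tolerant = TRUE` the ground truth is dilated by 1 px before
#' comparison, a common allowance for the limited precision of expert
#' delineations (off by default).
#'
#' @param pred predicted binary raster or a `vessel_map` (its `vp_mask`).
#' @param gt ground-truth binary raster.
#' @param fov logical field-of-view mask.
#' @param tolerant dilate `gt` by 1 px before counting.
#' @return named list `TP`, `FP`, `TN`, `FN`, `SE`, `SP` (`SE`/`SP` are
#'   `NaN` when undefined).
#' @export
confusion <- function(pred, gt, fov, tolerant = FALSE) {
  if (inherits(pred, "vessel_map")) pred <- pred$vp_mask
  pred <- pred != 0; gt <- gt != 0
  stopifnot(all(dim(pred) == dim(gt)), all(dim(pred) == dim(fov)))
  if (!any(fov)) stop("empty field of view")
  if (tolerant) {
    b <- matrix(1, 3, 3)
    gt <- as.matrix(EBImage::dilate(gt + 0, b)) > 0
  }
  p <- pred[fov]; g <- gt[fov]
  TP <- sum(p & g); FP <- sum(p & !g); TN <- sum(!p & !g); FN <- sum(!p & g)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       SE = if (TP + FN > 0) TP / (TP + FN) else NaN,
       SP = if (FP + TN > 0) TN / (FP + TN) else NaN)
}

#' ROC sweep over the detection parameter grid
#'
#' Runs guided detection over a grid of parameter pairs `(r_L, th_mfr)` —
#' the local-area radius and the MFR threshold fraction that the ROC
#' curves are tuned by — and records one (SP, SE) point per pair. The
#' matched-filter responses are computed once per `r_L`-independent site
#' set and re-thresholded, so the sweep costs little more than one guided
#' run. Points with undefined SE (degenerate ground truth) are flagged and
#' excluded.
#'
#' @param img the preprocessed [grey_image].
#' @param wall a [build_wall_map] result.
#' @param bank an [make_bank] bank.
#' @param gt ground-truth vessel raster.
#' @param r_L_values,th_mfr_values grid of parameter values.
#' @param full use the full-scan baseline instead of guided detection.
#' @return an `roc_curve`: data.frame with columns `sp`, `se`, `r_L`,
#'   `th_mfr`, sorted by `sp`.
#' @export
roc_sweep <- function(img, wall, bank, gt,
                      r_L_values = c(10, 15), th_mfr_values = seq(0.25, 2, by = 0.25),
                      full = FALSE) {
  img <- as_grey_image(img)
  pts <- data.frame(sp = numeric(0), se = numeric(0),
                    r_L = numeric(0), th_mfr = numeric(0))
  dense <- if (full) mfr_dense(img, bank) else NULL
  for (r_L in r_L_values) {
    for (th in th_mfr_values) {
      cm <- if (full) {
        st <- local_gl_stats(img, r_L = r_L)
        mu <- mean(dense$response[img$fov])
        vp <- img$fov & dense$response > th * mu &
          gl_interval_ok(img$pixels, st$mu_L)
        confusion(vp, gt, img$fov)
      } else {
        det <- guided_detect(img, wall, bank, th_mfr = th, r_L = r_L)
        confusion(det$vessel_map, gt, img$fov)
      }
      if (is.nan(cm$SE) || is.nan(cm$SP)) next
      pts <- rbind(pts, data.frame(sp = cm$SP, se = cm$SE,
                                   r_L = r_L, th_mfr = th))
    }
  }
  pts <- pts[order(pts$sp, -pts$se), , drop = FALSE]
  structure(pts, class = c("roc_curve", "data.frame"))
}

#' Reliability area of an ROC curve
#'
#' The area between the achieved curve `SE = f(SP)` and the chance
#' diagonal: the trapezoidal integral of SE over SP minus the chance
#' triangle area of one half, after extending the measured curve to the
#' conventional endpoints `(SP = 0, SE = 1)` (labelling everything vessel
#' is always available) and `(SP = 1, SE = 0)` where they were not
#' measured; duplicate SP values collapse to their maximal SE. A perfect
#' detector — which attains `(SP = 1, SE = 1)` — scores 0.5, a chance
#' detector 0; the result does not depend on input point order.
#'
#' @param roc an [roc_sweep] result or any data.frame with `sp`, `se`.
#' @return the reliability area, a number in \[-0.5, 0.5\].
#' @export
reliability <- function(roc) {
  sp <- roc$sp; se <- roc$se
  if (length(sp) < 1L) stop("need at least one ROC point")
  keep <- !is.na(sp) & !is.na(se)
  sp <- sp[keep]; se <- se[keep]
  # dedupe by max SE, then extend to the conventional endpoints
  agg <- tapply(se, sp, max)
  sp <- as.numeric(names(agg)); se <- as.numeric(agg)
  ord <- order(sp)
  sp <- sp[ord]; se <- se[ord]
  if (min(sp) > 0) { sp <- c(0, sp); se <- c(1, se) }
  if (max(sp) < 1) { sp <- c(sp, 1); se <- c(se, 0) }
  auc <- sum(diff(sp) * (utils::head(se, -1) + utils::tail(se, -1)) / 2)
  # minus the chance-triangle area between the endpoints: one half
  auc - 0.5
}

#' Guided versus full-scan site accounting
#'
#' Reports how many pixel sites each scan convolved and the resulting
#' search-space compression: the guided/full ratio and the guided site
#' fraction of the FOV.
#'
#' @param guided,full `mfr_field` results of the two scans.
#' @param fov logical field-of-view mask.
#' @return list: `full_sites`, `guided_sites`, `ratio`, `mask_fraction`.
#' @export
site_accounting <- function(guided, full, fov) {
  list(full_sites = full$sites_evaluated,
       guided_sites = guided$sites_evaluated,
       ratio = if (full$sites_evaluated > 0)
         guided$sites_evaluated / full$sites_evaluated else 0,
       mask_fraction = guided$sites_evaluated / sum(fov))
}
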