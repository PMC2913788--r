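#' Default pipeline configuration
#'
#' The full parameter set of the two-stage detector, with defaults.
#' Serialises round-trip identically to and from YAML ([read_config],
#' [write_config]). Any sub-list entry may be overridden via `...`, e.g.
#' `pipeline_config(detect = list(th_mfr = 1))`.
#'
#' @param ... named sub-lists merged over the defaults.
#' @return a nested `pipeline_config` list with components `preprocess`,
#'   `gradient`, `sgld`, `wall`, `mf`, `detect`, `eval` and `seed`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preprocess = list(kernel_size = 8, background_window = 200),
    gradient = list(neighborhood = 4, thr_scope = 0.5, deviation_form = FALSE),
    sgld = list(d_range = c(2, 30), candidate_widths = c(16, 32, 64),
                use_sgld_widths = TRUE),
    wall = list(width_range = c(5, 50), percentile_thr = 0.75,
                angle_tol = 20, inclusion_radius = 15, min_size = 10,
                prune_mode = "region_growing"),
    mf = list(n_angles = 12, n_scales = 4, sigma_along = 4,
              mode = "single_mode", sided = "double_sided",
              as_printed = FALSE),
    detect = list(th_mfr = 0.5, r_L = 15, max_bad_fraction = 0.25,
                  gap_max = 5),
    eval = list(r_L_values = c(10, 15),
                th_mfr_values = seq(0.25, 2, by = 0.25)),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the complete detection pipeline
#'
#' Executes the stages in order: preprocessing (smoothing, illumination
#' correction, FOV masking), then in parallel branches the gradient
#' features and the SGLD displacement analysis, then wall-map construction,
#' matched-filter bank tuning (scales from the SGLD width estimates when
#' available), guided and/or full-scan detection, and — when ground truth
#' is supplied — confusion, ROC and reliability evaluation. Every stage's
#' output is returned; artifacts are persisted when `out_dir` is given.
#'
#' @param image a [grey_image], numeric matrix, `synthetic_scene`, or path
#'   to an image file.
#' @param config a [pipeline_config].
#' @param gt optional ground-truth vessel raster (taken from the scene when
#'   `image` is a `synthetic_scene`).
#' @param mode `"guided"`, `"full"` or `"both"`.
#' @param out_dir optional artifact directory.
#' @param sweep_roc also run the ROC parameter sweep (needs `gt`).
#' @return list with elements `image` (preprocessed), `field`, `widths`
#'   (SGLD estimate data.frame), `wall`, `bank`, `guided`, `full` (each a
#'   list of `vessel_map` + `mfr`, as requested), `sites` (site
#'   accounting, when both scans ran), `confusion`, `roc`, `reliability`
#'   (when `gt` given) and `config`.
#' @export
run_pipeline <- function(image, config = pipeline_config(), gt = NULL,
                         mode = c("guided", "full", "both"),
                         out_dir = NULL, sweep_roc = FALSE) {
  mode <- match.arg(mode)
  cfg <- config
  set.seed(cfg$seed)
  if (is.character(image)) image <- read_image(image)
  if (inherits(image, "synthetic_scene")) {
    if (is.null(gt)) gt <- image$vessel_mask
    image <- image$image
  }
  img <- as_grey_image(image)
  if (all(img$fov)) img <- fov_ellipse_mask(img)

  img <- smooth_image(img, cfg$preprocess$kernel_size)
  img <- correct_illumination(img, cfg$preprocess$background_window)

  field <- compute_gradient(img)
  wall <- build_wall_map(img, field,
                         width_range = cfg$wall$width_range,
                         percentile_thr = cfg$wall$percentile_thr,
                         angle_tol = cfg$wall$angle_tol,
                         inclusion_radius = cfg$wall$inclusion_radius,
                         min_size = cfg$wall$min_size,
                         prune_mode = cfg$wall$prune_mode)

  widths <- NULL
  bank_widths <- cfg$sgld$candidate_widths
  if (isTRUE(cfg$sgld$use_sgld_widths) && any(wall$mask)) {
    widths <- tryCatch(
      estimate_dominant_widths(img, wall$mask,
                               d_magnitudes = seq(cfg$sgld$d_range[1],
                                                  cfg$sgld$d_range[2]),
                               candidate_set = cfg$sgld$candidate_widths),
      error = function(e) NULL)
    # a scene mixing many vessel orientations defeats the single-direction
    # displacement scan; only confident estimates may narrow the bank
    conf <- widths[!is.na(widths$snapped) & !widths$low_confidence, , drop = FALSE]
    if (!is.null(widths) && nrow(conf) > 0)
      bank_widths <- sort(unique(conf$snapped))
  }
  bank <- make_bank(bank_widths, n_angles = cfg$mf$n_angles,
                    n_scales = cfg$mf$n_scales,
                    sigma_along = cfg$mf$sigma_along,
                    mode = cfg$mf$mode, sided = cfg$mf$sided,
                    as_printed = cfg$mf$as_printed)

  out <- list(image = img, field = field, widths = widths, wall = wall,
              bank = bank, config = cfg)
  if (mode %in% c("guided", "both"))
    out$guided <- guided_detect(img, wall, bank,
                                th_mfr = cfg$detect$th_mfr,
                                r_L = cfg$detect$r_L,
                                max_bad_fraction = cfg$detect$max_bad_fraction,
                                gap_max = cfg$detect$gap_max)
  if (mode %in% c("full", "both"))
    out$full <- full_scan_detect(img, bank, th_mfr = cfg$detect$th_mfr,
                                 r_L = cfg$detect$r_L)
  if (!is.null(out$guided) && !is.null(out$full))
    out$sites <- site_accounting(out$guided$mfr, out$full$mfr, img$fov)

  if (!is.null(gt)) {
    pred <- (out$guided %||% out$full)$vessel_map
    out$confusion <- confusion(pred, gt, img$fov)
    if (sweep_roc) {
      out$roc <- roc_sweep(img, wall, bank, gt,
                           r_L_values = cfg$eval$r_L_values,
                           th_mfr_values = cfg$eval$th_mfr_values,
                           full = (mode == "full"))
      out$reliability <- reliability(out$roc)
    }
  }

  if (!is.null(out_dir)) write_artifacts(out, out_dir, gt = gt)
  out
}

#' @noRd
write_artifacts <- function(out, dir, gt = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grey_png(out$image, file.path(dir, "preprocessed.png"))
  write_mask_png(out$wall$mask, file.path(dir, "vwp_mask.png"))
  utils::write.csv(out$wall$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  det <- out$guided %||% out$full
  if (!is.null(det)) {
    write_mask_png(det$vessel_map$vp_mask, file.path(dir, "vp_mask.png"))
    write_mask_png(det$vessel_map$centerline, file.path(dir, "centerline.png"))
    wm <- which(!is.na(det$vessel_map$width_map), arr.ind = TRUE)
    utils::write.csv(data.frame(i = wm[, 1], j = wm[, 2],
                                width = det$vessel_map$width_map[wm]),
                     file.path(dir, "width_map.csv"), row.names = FALSE)
  }
  report <- list(provenance = if (!is.null(det)) det$vessel_map$provenance else NA,
                 wall_pixels = sum(out$wall$mask),
                 n_pairs = nrow(out$wall$pairs),
                 mask_fraction = sum(out$wall$mask) / sum(out$image$fov),
                 sites = out$sites,
                 confusion = out$confusion,
                 reliability = out$reliability)
  if (!is.null(out$guided))
    report$guided_sites <- out$guided$mfr$sites_evaluated
  if (!is.null(out$full))
    report$full_sites <- out$full$mfr$sites_evaluated
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(out$roc))
    utils::write.csv(as.data.frame(out$roc), file.path(dir, "roc.csv"),
                     row.names = FALSE)
  invisible(dir)
}
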