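#' Configuration for a synthetic fundus scene
#'
#' Describes a fundus-like test scene: a handful of dark, tubular vessel
#' segments with smooth cross-section profiles drawn inside an elliptical
#' field of view, over a bright background with a smooth illumination ramp,
#' bright drusen-like blobs, and additive Gaussian noise. The seed fully
#' determines the scene.
#'
#' Widths are the geometric tube widths in pixels (distance between the two
#' wall inflection points of the rendered profile). The default range 5-50
#' px spans the span of vessel calibres the wall-pairing stage accepts.
#'
#' @param height,width frame size in pixels.
#' @param n_vessels number of vessel segments.
#' @param width_range numeric length-2, min/max vessel width in px.
#' @param length_range numeric length-2, min/max centerline length in px.
#' @param profile cross-section shape: `"single_gaussian"` (bell),
#'   `"dual_mode"` (two offset wall peaks), `"single_sided"` (sigmoid step
#'   tube with flat lumen).
#' @param vessel_contrast lumen darkening in grey levels.
#' @param background_level mean background grey level.
#' @param background_gradient_amplitude peak-to-peak amplitude of the smooth
#'   illumination ramp, grey levels.
#' @param n_drusen number of bright blob distractors.
#' @param drusen_radius_range numeric length-2, blob radius range in px.
#' @param drusen_contrast blob brightening in grey levels.
#' @param noise_sigma additive Gaussian noise SD in grey levels.
#' @param max_turn per-step curvature cap for centerlines, radians per px.
#' @param seed integer RNG seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(height = 605, width = 700,
                         n_vessels = 15,
                         width_range = c(5, 50),
                         length_range = c(150, 250),
                         profile = c("single_gaussian", "dual_mode", "single_sided"),
                         vessel_contrast = 60,
                         background_level = 150,
                         background_gradient_amplitude = 25,
                         n_drusen = 8,
                         drusen_radius_range = c(4, 12),
                         drusen_contrast = 25,
                         noise_sigma = 5,
                         max_turn = 0.02,
                         seed = 1L) {
  profile <- match.arg(profile)
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_vessels = as.integer(n_vessels),
              width_range = as.numeric(width_range),
              length_range = as.numeric(length_range),
              profile = profile,
              vessel_contrast = vessel_contrast,
              background_level = background_level,
              background_gradient_amplitude = background_gradient_amplitude,
              n_drusen = as.integer(n_drusen),
              drusen_radius_range = as.numeric(drusen_radius_range),
              drusen_contrast = drusen_contrast,
              noise_sigma = noise_sigma,
              max_turn = max_turn,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

#' @noRd
validate_scene_config <- function(cfg) {
  if (cfg$height <= 0 || cfg$width <= 0) stop("zero-area image")
  wr <- cfg$width_range
  if (length(wr) != 2L || wr[1] > wr[2]) stop("width_range must be ordered [min,max]")
  if (wr[1] < 1 || wr[2] > min(cfg$height, cfg$width) / 4)
    stop("width_range outside [1, min(height,width)/4]")
  if (cfg$n_vessels < 0 || cfg$n_drusen < 0) stop("counts must be non-negative")
  if (cfg$noise_sigma < 0) stop("noise_sigma must be non-negative")
  invisible(cfg)
}

# Bounded-curvature random centerline: a unit-step heading walk whose
# turning rate is a smooth AR(1) sequence capped at max_turn rad/px, so the
# tube stays locally quasi-linear and wall pairing stays well posed.
#' @noRd
walk_centerline <- function(start, theta0, len, max_turn, inside) {
  pts <- matrix(NA_real_, nrow = len, ncol = 2)
  p <- start; th <- theta0; turn <- 0
  for (t in seq_len(len)) {
    if (!inside(p)) { pts <- pts[seq_len(t - 1L), , drop = FALSE]; break }
    pts[t, ] <- p
    turn <- clamp(0.9 * turn + stats::rnorm(1, 0, max_turn / 2), -max_turn, max_turn)
    th <- th + turn
    p <- p + c(sin(th), cos(th))
  }
  pts[stats::complete.cases(pts), , drop = FALSE]
}

#' Generate a synthetic fundus scene with ground truth
#'
#' Renders the scene described by a [scene_config]: vessel centerlines are
#' bounded-curvature random walks inside the FOV ellipse; each vessel is a
#' tube of constant width whose cross-section follows the configured
#' profile; the background is a constant level plus a smooth illumination
#' ramp plus drusen-like bright blobs; i.i.d. Gaussian noise is added and
#' the result is rounded to 8-bit grey levels.
#'
#' Ground truth: `vessel_mask` is the set of pixels within half a width of
#' a centerline, `wall_mask` its inner 1-px boundary ring, `centerline_mask`
#' the rasterised centerlines and `width_map` the per-centerline-pixel tube
#' width. All profiles place their steepest grey-level transition at the
#' geometric wall (half-width from the centerline), so gradient maxima sit
#' on `wall_mask`.
#'
#' @param config a [scene_config].
#' @return a `synthetic_scene` list: `image` ([grey_image]), `vessel_mask`,
#'   `wall_mask`, `centerline_mask` (logical matrices), `width_map` (numeric
#'   matrix, `NA` off the centerline) and `config`.
#' @examples
#' sc <- generate_scene(scene_config(height = 96, width = 96, n_vessels = 1,
#'                                   width_range = c(8, 8), length_range = c(60, 60),
#'                                   n_drusen = 0, noise_sigma = 0, seed = 7))
#' sum(sc$vessel_mask)
#' @export
generate_scene <- function(config) {
  cfg <- if (inherits(config, "scene_config")) config else do.call(scene_config, config)
  validate_scene_config(cfg)
  set.seed(cfg$seed)
  nr <- cfg$height; nc <- cfg$width

  fov <- ellipse_mask(nr, nc)
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  ai <- (nr - 1) / 2; aj <- (nc - 1) / 2

  vessel_mask <- matrix(FALSE, nr, nc)
  wall_mask <- matrix(FALSE, nr, nc)
  centerline_mask <- matrix(FALSE, nr, nc)
  width_map <- matrix(NA_real_, nr, nc)
  vessel_depth <- matrix(0, nr, nc)   # GL darkening accumulated over vessels

  widths <- stats::runif(max(cfg$n_vessels, 1L), cfg$width_range[1], cfg$width_range[2])
  lens <- round(stats::runif(max(cfg$n_vessels, 1L), cfg$length_range[1], cfg$length_range[2]))

  for (v in seq_len(cfg$n_vessels)) {
    w <- widths[v]
    margin <- w / 2 + 3
    inside <- function(p) {
      ((p[1] - ci) / max(ai - margin, 1))^2 + ((p[2] - cj) / max(aj - margin, 1))^2 <= 1
    }
    # rejection-sample a start point well inside the FOV
    repeat {
      start <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      if (inside(start)) break
    }
    theta0 <- stats::runif(1, 0, 2 * pi)
    pts <- walk_centerline(start, theta0, lens[v], cfg$max_turn, inside)
    if (nrow(pts) < 10L) next

    ipts <- unique(cbind(round(pts[, 1]), round(pts[, 2])))
    ok <- ipts[, 1] >= 1 & ipts[, 1] <= nr & ipts[, 2] >= 1 & ipts[, 2] <= nc
    ipts <- ipts[ok, , drop = FALSE]
    cl <- matrix(FALSE, nr, nc)
    cl[ipts] <- TRUE
    centerline_mask[ipts] <- TRUE
    width_map[ipts] <- w

    # distance of every pixel to this vessel's centerline
    dist <- as.matrix(EBImage::distmap(1 - cl))
    amp <- profile_amplitude(dist, w, cfg$profile)
    vessel_depth <- pmax(vessel_depth, cfg$vessel_contrast * amp)

    # tube of width w: pixels within half a width of the centerline; the
    # profile inflection (gradient ridge) sits on the tube boundary
    vm <- dist <= w / 2
    vessel_mask <- vessel_mask | vm
    wall_mask <- wall_mask | (vm & dist > w / 2 - 1.2)
  }
  wall_mask <- wall_mask & !centerline_mask

  # background: constant + smooth tilted ramp + drusen-like bright blobs
  phi <- stats::runif(1, 0, 2 * pi)
  ii <- matrix(seq_len(nr), nr, nc); jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ramp <- (cos(phi) * (ii - ci) / nr + sin(phi) * (jj - cj) / nc)
  if (diff(range(ramp)) > 0)
    ramp <- (ramp - min(ramp)) / diff(range(ramp)) - 0.5
  bg <- cfg$background_level + cfg$background_gradient_amplitude * ramp

  if (cfg$n_drusen > 0) {
    for (d in seq_len(cfg$n_drusen)) {
      repeat {
        pc <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
        if (((pc[1] - ci) / (0.9 * ai))^2 + ((pc[2] - cj) / (0.9 * aj))^2 <= 1) break
      }
      rad <- stats::runif(1, cfg$drusen_radius_range[1], cfg$drusen_radius_range[2])
      d2 <- (ii - pc[1])^2 + (jj - pc[2])^2
      bg <- bg + cfg$drusen_contrast * exp(-d2 / (2 * (rad / 1.5)^2))
    }
  }

  img <- bg - vessel_depth
  if (cfg$noise_sigma > 0)
    img <- img + stats::rnorm(nr * nc, 0, cfg$noise_sigma)
  img <- round(clamp(img, 0, 255))
  img[!fov] <- 0

  structure(list(image = grey_image(img, fov),
                 vessel_mask = vessel_mask & fov,
                 wall_mask = wall_mask & fov,
                 centerline_mask = centerline_mask & fov,
                 width_map = width_map,
                 config = cfg),
            class = "synthetic_scene")
}

# Cross-section amplitude in [0,1] as a function of distance d from the
# centerline, for tube width w. Every profile has its inflection (steepest
# descent) at d = w/2 so the rendered wall coincides with the mask wall.
#' @noRd
profile_amplitude <- function(d, w, profile) {
  switch(profile,
    single_gaussian = exp(-d^2 / (2 * (w / 2)^2)),
    dual_mode = {
      # wall-accentuated: lumen plateau plus two brighter-edge dips is
      # modelled as the sum of a core bell and wall bumps
      core <- 0.7 * exp(-d^2 / (2 * (w / 2)^2))
      edge <- 0.5 * exp(-(d - w / 2)^2 / (2 * (w / 6)^2))
      pmin(core + edge, 1)
    },
    single_sided = 1 / (1 + exp((d - w / 2) / (w / 12))),
    stop("unknown profile: ", profile)
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d, %d vessels, vessel fraction %.3f\n",
              nrow(x$vessel_mask), ncol(x$vessel_mask), x$config$n_vessels,
              mean(x$vessel_mask[x$image$fov])))
  invisible(x)
}

#' Largest ellipse inscribed in a frame
#' @param nr,nc frame size.
#' @return logical matrix, TRUE inside the inscribed ellipse.
#' @export
ellipse_mask <- function(nr, nc) {
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  ai <- (nr - 1) / 2; aj <- (nc - 1) / 2
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((ii - ci) / ai)^2 + ((jj - cj) / aj)^2 <= 1
}

#' Write a synthetic scene to a directory
#'
#' Writes `image.png`, `vessel_mask.png`, `wall_mask.png`, `centerline.png`
#' (masks as 0/255 PNG) and `scene.json` recording the configuration.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_grey_png(scene$image, file.path(dir, "image.png"))
  write_mask_png(scene$vessel_mask, file.path(dir, "vessel_mask.png"))
  write_mask_png(scene$wall_mask, file.path(dir, "wall_mask.png"))
  write_mask_png(scene$centerline_mask, file.path(dir, "centerline.png"))
  jsonlite::write_json(unclass(scene$config), file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
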