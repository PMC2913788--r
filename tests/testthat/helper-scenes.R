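# Analytic fixtures built in code: a straight tube with a chosen
# cross-section profile, and small canned scenes.

# Horizontal dark tube centred on row `row`, Gaussian bell profile with
# inflection at width/2; background constant. No RNG involved.
straight_tube <- function(nr = 96, nc = 96, width = 10, row = NULL,
                          bg = 150, contrast = 60,
                          profile = c("gaussian", "step")) {
  profile <- match.arg(profile)
  if (is.null(row)) row <- round(nr / 2)
  d <- abs(matrix(seq_len(nr), nr, nc) - row)
  amp <- switch(profile,
    gaussian = exp(-d^2 / (2 * (width / 2)^2)),
    step = 1 / (1 + exp((d - width / 2) / (width / 12))))
  img <- round(bg - contrast * amp)
  list(image = grey_image(img),
       vessel_mask = d <= width / 2,
       centerline_mask = d == 0,
       width = width, row = row)
}

# two antiparallel vertical step edges `sep` px apart (bright-dark-bright)
step_edges <- function(nr = 64, nc = 96, sep = 20, col = 40,
                       bg = 180, dark = 60, soft = 2) {
  j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  s <- function(x) 1 / (1 + exp(-x / soft))
  img <- bg - (bg - dark) * (s(j - col) - s(j - col - sep))
  grey_image(round(img))
}

# canned small noiseless scene used by several tests
tube_scene <- function(seed = 3, width = 8) {
  generate_scene(scene_config(height = 160, width = 160, n_vessels = 1,
                              width_range = c(width, width),
                              length_range = c(120, 120), n_drusen = 0,
                              noise_sigma = 0,
                              background_gradient_amplitude = 0,
                              seed = seed))
}

expect_mask <- function(x) {
  expect_true(is.logical(x) || all(x %in% c(0, 1)))
}
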