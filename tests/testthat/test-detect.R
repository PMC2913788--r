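wall_and_bank <- function(sc, width_range = c(5, 20), bank_width = NULL) {
  img <- smooth_image(sc$image, 8)
  wall <- build_wall_map(img, width_range = width_range)
  bank <- make_bank(bank_width %||% sc$config$width_range[1])
  list(img = img, wall = wall, bank = bank)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("guided detection segments a clean tube accurately", {
  sc <- tube_scene(seed = 3, width = 8)
  s <- wall_and_bank(sc, bank_width = 8)
  det <- guided_detect(s$img, s$wall, s$bank)
  cm <- confusion(det$vessel_map, sc$vessel_mask, s$img$fov)
  expect_gte(cm$SE, 0.9)
  expect_gte(cm$SP, 0.99)
  expect_equal(det$vessel_map$provenance, "guided")
  # centerline stays within 1 px of the true centerline
  dgt <- as.matrix(EBImage::distmap(1 - sc$centerline_mask))
  clp <- which(det$vessel_map$centerline, arr.ind = TRUE)
  expect_lte(max(dgt[clp]), 1)
  # width estimates along the centerline track the true width
  wvals <- det$vessel_map$width_map[!is.na(det$vessel_map$width_map)]
  expect_lt(mean(abs(wvals - 8)), 2)
})

test_that("guided detection degenerates gracefully", {
  sc <- tube_scene(seed = 3, width = 8)
  s <- wall_and_bank(sc, bank_width = 8)
  # an impossible threshold empties the vessel map
  det <- guided_detect(s$img, s$wall, s$bank, th_mfr = 1e9)
  expect_equal(sum(det$vessel_map$vp_mask), 0)
  # an empty wall map warns and returns an empty map
  empty_wall <- s$wall
  empty_wall$mask[] <- FALSE
  empty_wall$pairs <- empty_wall$pairs[0, ]
  expect_warning(det0 <- guided_detect(s$img, empty_wall, s$bank), "empty")
  expect_equal(sum(det0$vessel_map$vp_mask), 0)
  expect_equal(det0$mfr$sites_evaluated, 0L)
})

test_that("convolution sites are exactly the distinct pair midpoints", {
  sc <- tube_scene(seed = 13, width = 10)
  s <- wall_and_bank(sc, bank_width = 10)
  det <- guided_detect(s$img, s$wall, s$bank)
  pr <- s$wall$pairs
  mids <- unique(cbind(round((pr$ai + pr$bi) / 2), round((pr$aj + pr$bj) / 2)))
  expect_equal(det$mfr$sites_evaluated, nrow(mids))
  expect_lte(det$mfr$sites_evaluated, nrow(pr))
})

test_that("vessel pixel count is monotone in the response threshold", {
  sc <- tube_scene(seed = 19, width = 12)
  s <- wall_and_bank(sc, bank_width = 12)
  sizes <- vapply(c(0.25, 0.75, 1.25, 2), function(th)
    sum(guided_detect(s$img, s$wall, s$bank, th_mfr = th)$vessel_map$vp_mask),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("interior filling accepts lumen chords and drops false pairings", {
  tube <- straight_tube(96, 96, width = 12)
  img <- tube$image
  r <- tube$row
  # true chord across the dark lumen
  good <- data.frame(ai = r - 6, aj = 48, bi = r + 6, bj = 48,
                     distance = 12, angle = pi / 2, quality = 1)
  # false chord across bright background far from the tube
  bad <- data.frame(ai = 10, aj = 20, bi = 22, bj = 20,
                    distance = 12, angle = pi / 2, quality = 1)
  fl <- fill_interior(rbind(good, bad), img)
  expect_true(fl$kept[1])
  expect_false(fl$kept[2])
  expect_gt(sum(fl$vp_mask), 5)
  # a degenerate unit pair is judged by its own pixel
  tiny <- data.frame(ai = r, aj = 30, bi = r, bj = 31,
                     distance = 1, angle = 0, quality = 1)
  fl2 <- fill_interior(tiny, img)
  expect_true(fl2$kept[1])
})

test_that("centerline extraction interpolates missing pairs", {
  # straight synthetic pair list along a horizontal vessel with one gap
  cols <- setdiff(10:40, 25)
  pairs <- data.frame(ai = 15, aj = cols, bi = 25, bj = cols,
                      distance = 10, angle = pi / 2, quality = 1)
  wall <- structure(list(mask = matrix(TRUE, 40, 50), pairs = pairs,
                         inclusion_prob = NULL, candidates = NULL,
                         field = NULL),
                    class = "wall_pixel_map")
  cl <- extract_centerline(wall, gap_max = 5)
  expect_true(all(cl$centerline[cbind(20, cols)]))
  expect_true(cl$centerline[20, 25])  # bridged through the gap
  expect_equal(unname(cl$width_map[20, 25]), 10, tolerance = 1e-6)
  # no pairs, no centerline
  wall$pairs <- pairs[0, ]
  expect_equal(sum(extract_centerline(wall)$centerline), 0)
})

test_that("the full scan evaluates every FOV pixel and finds the tube", {
  sc <- tube_scene(seed = 3, width = 8)
  img <- smooth_image(sc$image, 8)
  bank <- make_bank(8, n_angles = 6, n_scales = 2)
  det <- full_scan_detect(img, bank)
  expect_identical(det$mfr$sites_evaluated, sum(img$fov))
  expect_equal(det$vessel_map$provenance, "full_scan")
  cm <- confusion(det$vessel_map, sc$vessel_mask, img$fov)
  expect_gte(cm$SE, 0.8)
})

test_that("guided and dense responses agree at shared sites", {
  sc <- tube_scene(seed = 13, width = 10)
  s <- wall_and_bank(sc, bank_width = 10)
  det <- guided_detect(s$img, s$wall, s$bank)
  dense <- mfr_dense(s$img, s$bank)
  expect_equal(det$mfr$response, dense$response[det$mfr$sites],
               tolerance = 1e-9)
})
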