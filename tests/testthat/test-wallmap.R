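test_that("candidate selection finds tube walls and nothing on flat images", {
  f <- compute_gradient(grey_image(matrix(99, 48, 48)))
  expect_equal(sum(candidate_wall_pixels(f)), 0)

  tube <- straight_tube(96, 96, width = 12)
  f <- compute_gradient(smooth_image(tube$image, 8))
  cand <- candidate_wall_pixels(f)
  # candidates are thin ridges on (or within 2 px of) the tube boundary
  d <- abs(matrix(seq_len(96), 96, 96) - tube$row)
  expect_true(all(abs(d[cand] - 6) <= 2.5))
  # both walls are traced along at least 80% of their length
  ridge <- d >= 5 & d <= 7
  near <- as.matrix(EBImage::distmap(1 - cand)) <= 1.5
  expect_gt(mean(near[ridge & f$fov]), 0.8)
})

test_that("a vacuous threshold admits every suppressed maximum", {
  set.seed(431)
  img <- grey_image(matrix(runif(64 * 64, 0, 255), 64, 64))
  f <- compute_gradient(img)
  all_max <- candidate_wall_pixels(f, percentile_thr = 0)
  gated <- candidate_wall_pixels(f, percentile_thr = 0.75)
  expect_true(all(gated <= all_max))
  expect_gt(sum(all_max), sum(gated))
})

test_that("antiparallel step edges pair at their separation", {
  img <- step_edges(sep = 20)
  f <- compute_gradient(smooth_image(img, 8))
  cand <- candidate_wall_pixels(f)
  pr <- pair_wall_pixels(cand, f, width_range = c(5, 50))
  expect_gt(nrow(pr), 30)  # roughly one pair per usable row
  expect_true(all(abs(pr$distance - 20) <= 2))

  # edges further apart than the accepted range cannot pair
  img60 <- step_edges(nc = 160, sep = 60, col = 40)
  f60 <- compute_gradient(smooth_image(img60, 8))
  pr60 <- pair_wall_pixels(candidate_wall_pixels(f60), f60,
                           width_range = c(5, 50))
  expect_lte(nrow(pr60), 2)

  # a single isolated edge has no partner at all
  one <- grey_image(matrix(rep(c(rep(180, 40), rep(60, 56)), each = 64), 64, 96))
  fo <- compute_gradient(smooth_image(one, 8))
  expect_equal(nrow(pair_wall_pixels(candidate_wall_pixels(fo), fo)), 0)
})

test_that("pairing is mutual and one-to-one", {
  sc <- tube_scene(seed = 13, width = 10)
  img <- smooth_image(sc$image, 8)
  f <- compute_gradient(img)
  pr <- pair_wall_pixels(candidate_wall_pixels(f), f, width_range = c(5, 20))
  keys <- c(paste(pr$ai, pr$aj), paste(pr$bi, pr$bj))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(pr$quality >= cos(20 * pi / 180) & pr$quality <= 1))
})

test_that("pair distances recover the rendered width", {
  for (w in c(8, 16)) {
    sc <- tube_scene(seed = 17, width = w)
    img <- smooth_image(sc$image, 8)
    f <- compute_gradient(img)
    pr <- pair_wall_pixels(candidate_wall_pixels(f), f, width_range = c(5, 30))
    expect_gt(nrow(pr), 20)
    expect_gt(mean(abs(pr$distance - w) <= 2), 0.8)
  }
})

test_that("gaussian inclusion applies per-feature two-sigma gates", {
  # crafted field: all features constant except the gradient magnitude,
  # whose neighbours spread symmetrically so the local sigma is exact
  nr <- 21; nc <- 61
  mask <- matrix(FALSE, nr, nc)
  cols <- seq(6, 56, by = 5)
  mask[11, cols] <- TRUE
  mag <- matrix(0, nr, nc)
  mag[11, cols] <- 100 + c(-2, 2, -2, 2, -2, 2, -2, 2, -2, 2, 0)
  sig <- sqrt(mean((c(-2, 2, -2, 2, -2, 2, -2, 2, -2, 2) - 0)^2))  # = 2
  field <- structure(list(mag = mag,
                          theta = matrix(0.3, nr, nc),
                          undefined = matrix(FALSE, nr, nc),
                          fov = matrix(TRUE, nr, nc)),
                     class = "gradient_field")
  img <- grey_image(matrix(120, nr, nc))

  # probe pixel at exactly 2 sigma: factor exp(-2), still accepted
  mag[11, cols[11]] <- 100 + 2 * sig
  field$mag <- mag
  inc <- gaussian_inclusion(img, field, mask, radius = 30, min_neighbors = 5)
  expect_true(inc$accept[11, cols[11]])
  expect_equal(inc$prob[11, cols[11]], exp(-2), tolerance = 1e-6)

  # at 3 sigma the pixel is rejected no matter the other features
  mag[11, cols[11]] <- 100 + 3 * sig
  field$mag <- mag
  inc <- gaussian_inclusion(img, field, mask, radius = 30, min_neighbors = 5)
  expect_false(inc$accept[11, cols[11]])
  expect_equal(inc$status[11, cols[11]], 2L)
})

test_that("inclusion keeps perfectly homogeneous pixels with probability 1", {
  nr <- 15; nc <- 40
  mask <- matrix(FALSE, nr, nc)
  mask[8, seq(4, 36, by = 4)] <- TRUE
  field <- structure(list(mag = matrix(5, nr, nc),
                          theta = matrix(1, nr, nc),
                          undefined = matrix(FALSE, nr, nc),
                          fov = matrix(TRUE, nr, nc)),
                     class = "gradient_field")
  inc <- gaussian_inclusion(grey_image(matrix(100, nr, nc)), field, mask,
                            radius = 20, min_neighbors = 5)
  expect_true(all(inc$accept[mask]))
  expect_true(all(abs(inc$prob[mask] - 1) < 1e-9))
})

test_that("sparse pruning removes small components and never adds pixels", {
  m <- matrix(FALSE, 64, 64)
  m[2, 2:4] <- TRUE                   # size 3
  m[10, 11:18] <- TRUE                # size 8
  m[20:39, 5] <- TRUE                 # size 20
  m[50:59, 30:34] <- TRUE             # size 50
  out <- prune_sparse(m, min_size = 10)
  expect_equal(sum(out), 70)
  lab <- EBImage::bwlabel(out + 0)
  expect_equal(max(lab), 2)
  expect_true(all(out <= m))

  expect_equal(sum(prune_sparse(matrix(FALSE, 8, 8))), 0)

  set.seed(432)
  rnd <- matrix(runif(64 * 64) < 0.1, 64, 64)
  expect_true(all(prune_sparse(rnd, min_size = 4) <= rnd))
})

test_that("constrained growth merges fragments along a support ridge", {
  m <- matrix(FALSE, 40, 40)
  support <- matrix(FALSE, 40, 40)
  support[20, 5:35] <- TRUE
  m[20, c(5:8, 15:18, 25:28)] <- TRUE  # three 4-px fragments, one ridge
  # without growth each fragment dies at min_size = 10
  expect_equal(sum(prune_sparse(m, min_size = 10)), 0)
  # with growth along the ridge they merge into one 12-px component
  out <- prune_sparse(m, min_size = 10, support = support, max_steps = 10)
  expect_equal(sum(out), 12)
})

test_that("hough pruning keeps line support and drops scatter", {
  set.seed(433)
  m <- matrix(FALSE, 64, 64)
  m[30, 10:49] <- TRUE  # a 40-px straight line
  singles <- cbind(sample(1:64, 20), sample(1:64, 20))
  singles <- singles[abs(singles[, 1] - 30) > 2, , drop = FALSE]
  m[singles] <- TRUE
  out <- prune_sparse(m, mode = "hough", min_votes = 20)
  expect_true(all(out[30, 10:49]))
  expect_equal(sum(out[singles]), 0)
})

test_that("the built wall map stays sparse on a fundus-like scene", {
  sc <- generate_scene(scene_config(height = 242, width = 280, n_vessels = 4,
                                    width_range = c(5, 25),
                                    length_range = c(60, 100), seed = 21))
  img <- correct_illumination(smooth_image(sc$image, 8))
  wall <- build_wall_map(img, width_range = c(5, 25))
  expect_lt(sum(wall$mask) / sum(img$fov), 0.02)
  expect_gt(nrow(wall$pairs), 50)
  # every surviving pair endpoint is in the mask
  expect_true(all(wall$mask[cbind(wall$pairs$ai, wall$pairs$aj)]))
  expect_true(all(wall$mask[cbind(wall$pairs$bi, wall$pairs$bj)]))
  # pair distances honour the configured range
  expect_true(all(wall$pairs$distance >= 5 & wall$pairs$distance <= 25))
})
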