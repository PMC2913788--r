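test_that("gradient of flat and ramp images is analytic", {
  f <- compute_gradient(grey_image(matrix(42, 20, 20)))
  expect_true(all(f$mag == 0))
  expect_true(all(f$undefined))

  ramp <- grey_image(matrix(seq_len(30), 30, 30, byrow = TRUE))  # I = j
  f <- compute_gradient(ramp)
  inner <- 3:28
  expect_equal(unname(f$gj[inner, inner]), matrix(1, 26, 26))
  expect_equal(unname(f$gi[inner, inner]), matrix(0, 26, 26))
  # orientation is perpendicular to the gradient: the vertical axis
  expect_true(all(abs(abs(f$oi[inner, inner])) == 1))
  expect_true(all(f$oj[inner, inner] == 0))
})

test_that("global gradient statistics match a double-loop oracle", {
  set.seed(411)
  m <- matrix(round(runif(32 * 32, 0, 255)), 32, 32)
  f <- compute_gradient(grey_image(m))
  # oracle: explicit summation with the same stencil conventions
  mags <- matrix(0, 32, 32)
  for (i in 2:31) for (j in 2:31) {
    gi <- (m[i + 1, j] - m[i - 1, j]) / 2
    gj <- (m[i, j + 1] - m[i, j - 1]) / 2
    mags[i, j] <- sqrt(gi^2 + gj^2)
  }
  expect_equal(f$global_mean_mag, mean(mags), tolerance = 1e-12)
  expect_equal(f$global_std, sqrt(mean((mags - mean(mags))^2)),
               tolerance = 1e-12)
  # orientation is unit length and orthogonal to the gradient direction
  ok <- !f$undefined
  expect_true(all(abs(f$oi[ok]^2 + f$oj[ok]^2 - 1) < 1e-9))
  expect_true(all(abs(f$oi[ok] * f$ui[ok] + f$oj[ok] * f$uj[ok]) < 1e-6))
})

test_that("gradient strength follows its closed form", {
  set.seed(412)
  img <- grey_image(matrix(runif(40 * 40, 0, 255), 40, 40))
  f <- compute_gradient(img)
  s <- gradient_strength(f, neighborhood_radius = 4)
  # zero-gradient pixel scores exactly A; at mag = sigma the factor is
  # exp(-1/2)
  expect_equal(exp(-f$global_std^2 / (2 * f$global_std^2)), exp(-0.5))
  # per-pixel re-evaluation of the formula
  A <- matrix(0, 40, 40)
  for (i in 1:40) for (j in 1:40) {
    wi <- max(1, i - 4):min(40, i + 4); wj <- max(1, j - 4):min(40, j + 4)
    A[i, j] <- max(f$mag[wi, wj])
  }
  expect_equal(s, A * exp(-f$mag^2 / (2 * f$global_std^2)), tolerance = 1e-12)
  # strictly decreasing in magnitude at fixed A
  r <- s / A
  ord <- order(f$mag)
  expect_true(all(diff(r[ord]) <= 1e-12))
  # deviation-form switch peaks at the mean magnitude instead
  sd_ <- gradient_strength(f, deviation_form = TRUE)
  expect_equal(sd_, A * exp(-(f$mag - f$global_mean_mag)^2 /
                              (2 * f$global_std^2)), tolerance = 1e-12)
})

test_that("constant gradient field degenerates with a warning", {
  f <- compute_gradient(grey_image(matrix(5, 16, 16)))
  expect_warning(s <- gradient_strength(f), "constant")
  expect_true(all(s == 0))  # A = 0 everywhere on a flat image
})

test_that("orientation scope is monotone in its threshold", {
  set.seed(413)
  img <- grey_image(matrix(runif(48 * 48, 0, 255), 48, 48))
  f <- compute_gradient(img)
  expect_true(all(orientation_scope(f, r_max = 6, thr = 0) == 6))
  lo <- orientation_scope(f, r_max = 6, thr = 0.3)
  hi <- orientation_scope(f, r_max = 6, thr = 0.6)
  expect_true(all(lo >= hi))
  # pure noise decorrelates quickly: most scopes stay small
  expect_lte(median(orientation_scope(f, r_max = 8, thr = 0.5)), 2)
})

test_that("scope covers the interior of a homogeneous tube", {
  tube <- straight_tube(64, 64, width = 12)
  f <- compute_gradient(smooth_image(tube$image, 8))
  sc <- orientation_scope(f, r_max = 8, thr = 0.5)
  on_wall <- abs(matrix(seq_len(64), 64, 64) - tube$row) == 6
  expect_gte(median(sc[on_wall]), 2)
})

test_that("local homogeneity maps match a sliding-window oracle", {
  set.seed(414)
  img <- grey_image(matrix(runif(24 * 24, 0, 255), 24, 24))
  f <- compute_gradient(img)
  h <- local_homogeneity(f, block = 8)
  r <- 4
  oracle <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24) {
    wi <- max(1, i - r):min(24, i + r); wj <- max(1, j - r):min(24, j + r)
    v <- f$mag[wi, wj]
    oracle[i, j] <- mean((v - mean(v))^2)
  }
  expect_equal(h$grad_var, oracle, tolerance = 1e-9)
  # constant-gradient ramp: all three variances vanish (interior)
  ramp <- grey_image(matrix(seq_len(30), 30, 30, byrow = TRUE))
  h0 <- local_homogeneity(compute_gradient(ramp), block = 8)
  inner <- 8:23
  expect_true(all(h0$grad_var[inner, inner] < 1e-9))
  expect_true(all(h0$orient_var[inner, inner] < 1e-9))
  expect_true(all(h0$curv_var[inner, inner] < 1e-9))
})

test_that("checkerboard orientations are maximally inhomogeneous", {
  # 2-px checkerboard: the central-difference stencil sees alternating
  # gradient axes (a 1-px board is invisible to central differences)
  chk <- grey_image(255 * outer(1:32, 1:32,
                                function(i, j) (i %/% 2 + j %/% 2) %% 2))
  h <- local_homogeneity(compute_gradient(chk), block = 8)
  expect_gt(mean(h$orient_var[9:24, 9:24]), 0.5)
})

test_that("orientation is rotation-equivariant on a tube", {
  tube <- straight_tube(64, 64, width = 10)  # horizontal: theta ~ 0
  f_h <- compute_gradient(smooth_image(tube$image, 8))
  f_v <- compute_gradient(smooth_image(grey_image(t(tube$image$pixels)), 8))
  wall <- abs(matrix(seq_len(64), 64, 64) - tube$row) == 5
  th_h <- f_h$theta[wall]
  th_v <- f_v$theta[t(wall)]
  ang <- function(x) pmin(x %% pi, pi - x %% pi)
  expect_lt(median(ang(th_h)), 0.05)
  expect_lt(median(ang(th_v - pi / 2)), 0.05)
})
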