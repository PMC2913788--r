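test_that("the raw kernel has its printed zero structure", {
  p <- mf_params(sigma_u = 6, sigma_v = 3, a_u = 3, a_v = 2, D = 10)
  k <- make_kernel(p, zero_dc = FALSE)
  H <- (nrow(k) - 1) / 2
  u <- matrix(-H:H, nrow(k), ncol(k), byrow = TRUE)  # angle 0: u = columns
  v <- matrix(-H:H, nrow(k), ncol(k))
  # zero crossings exactly at |u| = a_u and |v| = a_v
  expect_true(all(abs(k[abs(u) == 3]) < 1e-12))
  expect_true(all(abs(k[abs(v) == 2]) < 1e-12))
  # zero outside the support disk
  outside <- (u - 3)^2 + (v - 2)^2 > 10^2
  expect_true(all(k[outside] == 0))
  # and not identically zero inside
  expect_gt(max(abs(k)), 0)
})

test_that("unmodulated kernels are even and zero-DC", {
  p <- mf_params(sigma_u = 6, sigma_v = 3, D = 12)
  k <- make_kernel(p, zero_dc = FALSE)
  expect_equal(unclass(k), unclass(k)[rev(seq_len(nrow(k))), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(k), unclass(k)[, rev(seq_len(ncol(k)))],
               tolerance = 1e-12, ignore_attr = TRUE)
  # default construction removes the DC component
  for (kk in make_bank(c(16, 32), n_angles = 3, n_scales = 2)$kernels)
    expect_lt(abs(sum(kk)), 1e-9)
})

test_that("invalid kernel parameters are rejected", {
  expect_error(mf_params(sigma_u = 0, sigma_v = 1, D = 5), "positive")
  expect_error(mf_params(sigma_u = 1, sigma_v = 1, a_u = 6, D = 5), "smaller than D")
  expect_error(mf_params(sigma_u = 1, sigma_v = 1, a_u = -1, D = 5),
               "non-negative")
})

test_that("the bank has the configured geometry", {
  bank <- make_bank(16)
  expect_length(bank$kernels, 48)  # 12 angles x 4 scales
  expect_equal(sort(unique(bank$meta$angle_id)), 1:12)
  expect_equal(sort(unique(bank$meta$scale_id)), 1:4)

  single <- make_bank(16, n_angles = 1, n_scales = 1)
  expect_length(single$kernels, 1)
  sv <- 0.75 * single$meta$scale[1]
  ref <- make_kernel(mf_params(sigma_u = 4, sigma_v = sv,
                               D = max(8, 2 * sv), angle = 0))
  expect_equal(unclass(single$kernels[[1]]), unclass(ref),
               ignore_attr = TRUE)
})

test_that("a kernel responds most to the profile width it was built for", {
  for (kw in c(16, 32)) {
    b <- make_bank(kw, n_angles = 1, n_scales = 1)
    b$kernels[[1]] <- make_kernel(
      mf_params(sigma_u = 4, sigma_v = 0.75 * kw, D = 2 * 0.75 * kw))
    resp_on <- function(tw) {
      tube <- straight_tube(300, 128, width = tw)
      convolve_at(tube$image, b, matrix(c(tube$row, 64), 1))$response
    }
    r_match <- resp_on(kw)
    expect_gt(r_match, 0)  # dark tube yields a positive matched response
    expect_gte(r_match, resp_on(kw / 2))
    expect_gte(r_match, resp_on(2 * kw))
  }
})

test_that("site-restricted responses equal the dense oracle", {
  set.seed(441)
  img <- grey_image(matrix(round(runif(64 * 64, 0, 255)), 64, 64))
  bank <- make_bank(10, n_angles = 4, n_scales = 2)
  dense <- mfr_dense(img, bank)
  sites <- cbind(sample(10:54, 30, replace = TRUE),
                 sample(10:54, 30, replace = TRUE))
  sites <- sites[!duplicated(sites), , drop = FALSE]
  mfr <- convolve_at(img, bank, sites)
  expect_equal(mfr$response, dense$response[mfr$sites], tolerance = 1e-9)
  # arg-max ids may differ only where two kernels tie (the 2 pi angle grid
  # contains pairs of identical even kernels): wherever the ids disagree,
  # the two chosen kernels must be the same filter
  kid <- function(angle_id, scale_id)
    which(bank$meta$angle_id == angle_id & bank$meta$scale_id == scale_id)
  for (i in seq_len(nrow(mfr$sites))) {
    a <- kid(mfr$best_angle[i], mfr$best_scale[i])
    b <- kid(dense$best_angle[mfr$sites][i], dense$best_scale[mfr$sites][i])
    if (a != b)
      expect_equal(unclass(bank$kernels[[a]]), unclass(bank$kernels[[b]]),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("responses are invariant to bank order and count sites once", {
  set.seed(442)
  img <- grey_image(matrix(runif(48 * 48, 0, 255), 48, 48))
  bank <- make_bank(8, n_angles = 3, n_scales = 2)
  perm <- bank
  ord <- c(4, 2, 6, 1, 5, 3)
  perm$kernels <- bank$kernels[ord]
  perm$meta <- bank$meta[ord, ]
  sites <- cbind(c(24, 30, 24, 10), c(24, 30, 24, 40))  # one duplicate
  a <- convolve_at(img, bank, sites)
  b <- convolve_at(img, perm, sites)
  expect_equal(sort(a$response), sort(b$response))
  expect_equal(a$sites_evaluated, 3L)  # duplicate collapsed

  one <- convolve_at(img, bank, matrix(c(24, 24), 1))
  expect_equal(one$sites_evaluated, 1L)
  oob <- convolve_at(img, bank, rbind(c(24, 24), c(500, 500)))
  expect_equal(oob$sites_evaluated, 1L)
  expect_equal(oob$sites_skipped, 1L)
})

test_that("zero-DC kernels null flat backgrounds", {
  img <- grey_image(matrix(200, 40, 40))
  bank <- make_bank(8, n_angles = 2, n_scales = 1)
  mfr <- convolve_at(img, bank, matrix(c(20, 20), 1))
  expect_lt(abs(mfr$response), 1e-9)
})

test_that("rotated kernels respond consistently on rotated tubes", {
  tube <- straight_tube(96, 96, width = 12)
  kv <- make_bank(12, n_angles = 1, n_scales = 1)  # angle 0: along columns
  r_h <- convolve_at(tube$image, kv, matrix(c(tube$row, 48), 1))$response
  # transpose the scene: the tube now runs vertically; use the 90-degree
  # kernel
  k90 <- kv
  p <- attr(k90$kernels[[1]], "params"); p$angle <- pi / 2
  k90$kernels[[1]] <- make_kernel(p)
  r_v <- convolve_at(grey_image(t(tube$image$pixels)), k90,
                     matrix(c(48, tube$row), 1))$response
  expect_lt(abs(r_h - r_v) / abs(r_h), 0.02)
})

test_that("dual-mode and single-sided kernels build and stay zero-DC", {
  pd <- mf_params(sigma_u = 6, sigma_v = 3, D = 9, mode = "dual_mode")
  kd <- make_kernel(pd)
  expect_lt(abs(sum(kd)), 1e-9)
  ps <- mf_params(sigma_u = 6, sigma_v = 3, D = 9, sided = "single_sided")
  ks <- make_kernel(ps)
  expect_lt(abs(sum(ks)), 1e-9)
  H <- (nrow(ks) - 1) / 2
  v <- matrix(-H:H, nrow(ks), ncol(ks))
  expect_true(all(ks[v < 0] == 0))
})
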