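test_that("Otsu threshold matches an exhaustive between-class variance search", {
  set.seed(42)
  for (rep in 1:5) {
    v <- c(rnorm(60, 50, 8), rnorm(40, 180, 12))
    th <- otsu_threshold(v)
    # oracle: try every midpoint between adjacent sorted unique values
    sv <- sort(unique(v))
    cand <- (sv[-1] + sv[-length(sv)]) / 2
    bc <- vapply(cand, function(ct) {
      lo <- v[v <= ct]; hi <- v[v > ct]
      length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    }, numeric(1))
    best <- cand[which.max(bc)]
    # same partition: the histogram threshold separates the same two groups
    expect_identical(v > th, v > best)
  }
  expect_true(is.na(otsu_threshold(rep(7, 50))))
  # two-level histogram: threshold falls strictly between the modes
  th2 <- otsu_threshold(c(rep(50, 50), rep(200, 50)))
  expect_gt(th2, 50); expect_lt(th2, 200)
  # independent implementation cross-check on [0, 1]-scaled data
  v01 <- c(rep(0.2, 128), rep(0.8, 128))
  th_eb <- EBImage::otsu(EBImage::Image(matrix(v01, 16, 16)), range = c(0, 1))
  th_ours <- otsu_threshold(v01 * 255) / 255
  expect_identical(v01 > th_eb, v01 > th_ours)
})

test_that("candidate selection ranks by variance with id tie-breaks", {
  lab <- matrix(rep(1:10, each = 10), 10, 10)
  px <- matrix(0, 10, 10)
  sp <- superpixel_map(lab, px)
  expect_equal(select_candidates(sp, deepseg_params(variance_fraction = 0.2)), c(1L, 2L))
  expect_equal(sort(select_candidates(sp, deepseg_params(variance_fraction = 1))), 1:10)
  px2 <- px; px2[, 5] <- c(rep(0, 5), rep(100, 5))  # region 5 gets variance
  sp2 <- superpixel_map(lab, px2)
  expect_equal(select_candidates(sp2, deepseg_params(variance_fraction = 0.1)), 5L)
})

test_that("a balanced two-level region splits into its two components", {
  lab <- matrix(1L, 10, 10)
  px <- matrix(50, 10, 10); px[, 6:10] <- 200
  sp <- superpixel_map(lab, px)
  out <- split_superpixel(px, sp, 1L, deepseg_params(t = 0.2))
  expect_equal(out$K, 2L)
  expect_equal(sort(out$stats$n_px), c(50L, 50L))
  expect_setequal(round(out$stats$mean), c(50, 200))
  expect_true(validate_partition(out))
})

test_that("a minor-side fraction at or below t is not split off", {
  lab <- matrix(1L, 10, 10)
  px <- matrix(50, 10, 10); px[1:5, 10] <- 200  # 5 of 100 px
  sp <- superpixel_map(lab, px)
  out <- split_superpixel(px, sp, 1L, deepseg_params(t = 0.1))
  expect_equal(out$K, 1L)
  expect_identical(out$labels, sp$labels)
  # a constant region never splits
  spc <- superpixel_map(matrix(1L, 8, 8), matrix(9, 8, 8))
  expect_equal(split_superpixel(matrix(9, 8, 8), spc, 1L)$K, 1L)
  expect_error(split_superpixel(px, sp, 99L), "does not exist")
})

test_that("a superpixel straddling a tissue boundary splits along it", {
  px <- matrix(64, 24, 24); px[, 13:24] <- 192
  lab <- matrix(rep(c(1L, 2L, 3L), times = c(6, 12, 6)), 24, 24, byrow = TRUE)
  sp <- superpixel_map(lab, px)  # region 2 straddles the boundary
  out <- deep_segment(px, sp, deepseg_params(variance_fraction = 0.34))
  expect_gte(out$K, 4L)
  # every region is now pure in intensity
  for (id in out$stats$id) {
    expect_equal(out$stats$var[id], 0)
  }
  expect_true(validate_partition(out))
})

test_that("deep segmentation never decreases K and is idempotent once stable", {
  p <- small_phantom(size = 64, gs = 5L)
  sp <- evolve_turbopixels(p$image)
  d1 <- deep_segment(p$image, sp, deepseg_params())
  expect_gte(d1$K, sp$K)
  expect_true(validate_partition(d1))
  # piecewise-constant image: with enough rounds splitting reaches a fixed
  # point, after which repeated application is the identity
  dp8 <- deepseg_params(max_rounds = 8)
  d8 <- deep_segment(p$image, sp, dp8)
  d9 <- deep_segment(p$image, d8, dp8)
  expect_identical(d9$labels, d8$labels)
  # noisy input still yields a valid partition with K non-decreasing
  pn <- small_phantom(size = 64, noise = 5, bias = 20, gs = 5L)
  spn <- evolve_turbopixels(pn$image)
  dn <- deep_segment(pn$image, spn, deepseg_params())
  expect_gte(dn$K, spn$K)
  expect_true(validate_partition(dn))
  # variance_fraction 0 disables deep segmentation entirely
  expect_identical(deep_segment(p$image, sp, deepseg_params(variance_fraction = 0)), sp)
})
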