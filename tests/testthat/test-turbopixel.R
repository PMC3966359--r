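test_that("seeds stay on the lattice when the image is constant", {
  s <- place_seeds(gray_image(matrix(5, 32, 32)), 4)
  expect_equal(nrow(s), 4L)
  expect_setequal(s[, "row"], c(8L, 24L))
  expect_setequal(s[, "col"], c(8L, 24L))
  # single seed sits centrally
  s1 <- place_seeds(gray_image(matrix(5, 31, 31)), 1)
  expect_equal(unname(s1[1, ]), c(16L, 16L))
})

test_that("a seed landing on a bright line is perturbed off it", {
  px <- matrix(0, 32, 32)
  px[, 8] <- 255  # vertical line through a lattice column
  img <- gray_image(px)
  s <- place_seeds(img, 4)
  # each seed sits at the exhaustive-scan minimum of the edge-energy field
  # within the 3x3 window around its lattice site
  gm <- attr(s, "field")
  lattice <- rbind(c(8, 8), c(8, 24), c(24, 8), c(24, 24))
  for (k in seq_len(nrow(s))) {
    win <- expand.grid(r = (lattice[k, 1] - 1):(lattice[k, 1] + 1),
                       c = (lattice[k, 2] - 1):(lattice[k, 2] + 1))
    expect_equal(gm[s[k, 1], s[k, 2]], min(gm[as.matrix(win)]))
    expect_lte(max(abs(s[k, ] - lattice[k, ])), 1)
  }
  expect_true(all(s[, "col"] != 8L))
  expect_error(place_seeds(gray_image(matrix(1, 4, 4)), 17), "exceeds")
})

test_that("local affinity is 1 on flat regions and dips at an impulse", {
  p <- turbopixel_params()
  expect_true(all(local_affinity(gray_image(matrix(42, 16, 16)), p) == 1))
  px <- matrix(0, 21, 21); px[11, 11] <- 255
  phi <- local_affinity(gray_image(px), p)
  # oracle: evaluate E = g/(G_sigma*g + gamma) directly at the probe pixels
  g <- matrix(0, 21, 21)
  for (i in 2:20) for (j in 2:20) {
    g[i, j] <- sqrt(((px[i + 1, j] - px[i - 1, j]) / 2)^2 +
                    ((px[i, j + 1] - px[i, j - 1]) / 2)^2)
  }
  g <- g / max(g)
  expect_lt(min(phi), phi[1, 1])
  loc <- which(phi == min(phi), arr.ind = TRUE)[1, ]
  expect_true(all(abs(loc - 11) <= 1))  # minimum in the impulse neighbourhood
  expect_equal(phi[1, 1], 1)  # far corner untouched by the impulse
  # doubling nu raises the affinity pointwise
  phi2 <- local_affinity(gray_image(px), turbopixel_params(nu = 0.6))
  expect_true(all(phi2 >= phi))
})

test_that("image speed reduces to known closed forms", {
  p <- turbopixel_params()
  n <- 41L
  # planar front, constant affinity: both correction terms vanish
  psi <- matrix(rep(seq_len(n) - 20.5, n), n, n)
  si <- speed_si(list(psi = psi), matrix(1, n, n), p)
  expect_equal(si[10:30, 10:30], matrix(1, 21, 21))
  # circular front of radius r: S_I = 1 - alpha / r at the front
  r <- 20
  rowm <- matrix(seq_len(101), 101, 101); colm <- t(rowm)
  rho <- sqrt((rowm - 51)^2 + (colm - 51)^2)
  si_c <- speed_si(list(psi = r - rho), matrix(1, 101, 101), p)
  front <- abs(rho - r) < 0.5
  expect_equal(mean(si_c[front]), 1 - p$alpha / r, tolerance = 1e-3)
  # alpha = beta = 0 collapses to the affinity exactly
  phi <- matrix(runif(101 * 101), 101, 101)
  p0 <- turbopixel_params(alpha = 0, beta = 0)
  expect_equal(speed_si(list(psi = r - rho), phi, p0), phi)
})

test_that("proximity speed vanishes on the inter-region skeleton", {
  lab1 <- matrix(0L, 15, 15); lab1[8, 8] <- 1L
  expect_true(all(speed_sb(list(labels = lab1)) == 1))
  lab2 <- matrix(0L, 21, 21); lab2[11, 5] <- 1L; lab2[11, 17] <- 2L
  sb <- speed_sb(list(labels = lab2))
  # oracle: brute-force distances from each region
  d1 <- sqrt((row(lab2) - 11)^2 + (col(lab2) - 5)^2)
  d2 <- sqrt((row(lab2) - 11)^2 + (col(lab2) - 17)^2)
  expect_equal(sb, pmin(pmax((pmax(d1, d2) - pmin(d1, d2)) / 2, 0), 1))
  expect_true(all(sb[, 11] == 0))  # perpendicular bisector
  expect_equal(sb[11, 2], 1)
})

test_that("constant-image evolution approximates the Voronoi partition", {
  sp <- evolve_turbopixels(gray_image(matrix(50, 32, 32)), turbopixel_params(n_seeds = 4))
  expect_equal(sp$K, 4L)
  expect_true(all(abs(sp$stats$n_px - 256) <= 25.6))
  seeds <- attr(sp, "seeds")
  vor <- matrix(0L, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    vor[i, j] <- which.min((seeds[, 1] - i)^2 + (seeds[, 2] - j)^2)
  }
  expect_gte(mean(sp$labels == vor), 0.9)
  expect_true(validate_partition(sp))
})

test_that("a strong step edge pins the region boundary to the edge column", {
  px <- matrix(40, 32, 32); px[, 17:32] <- 200
  sp <- evolve_turbopixels(gray_image(px), turbopixel_params(n_seeds = 2))
  expect_equal(sp$K, 2L)
  left_lab <- sp$labels[1, 1]
  boundary <- vapply(1:32, function(i) max(which(sp$labels[i, ] == left_lab)), integer(1))
  expect_true(all(abs(boundary - 16L) <= 1L))
})

test_that("a single seed grows to cover the whole image", {
  sp <- evolve_turbopixels(gray_image(matrix(7, 24, 24)), turbopixel_params(n_seeds = 1))
  expect_equal(sp$K, 1L)
  expect_true(all(sp$labels == 1L))
})

test_that("evolution yields a valid partition with K <= L on varied images", {
  for (gs in c(3L, 7L)) {
    p <- small_phantom(size = 64, noise = 5, bias = 20, gs = gs)
    sp <- evolve_turbopixels(p$image)
    expect_lte(sp$K, round(64 * 64 / 256))
    expect_true(validate_partition(sp))
    expect_true(all(sp$stats$n_px >= 1L))
  }
})

test_that("region adjacency matches a brute-force neighbour scan", {
  p <- small_phantom(size = 48)
  sp <- evolve_turbopixels(p$image, turbopixel_params(n_seeds = 9))
  lab <- sp$labels
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    if (i < nrow(lab) && lab[i, j] != lab[i + 1, j]) {
      pairs <- rbind(pairs, sort(c(lab[i, j], lab[i + 1, j])))
    }
    if (j < ncol(lab) && lab[i, j] != lab[i, j + 1]) {
      pairs <- rbind(pairs, sort(c(lab[i, j], lab[i, j + 1])))
    }
  }
  pairs <- unique(pairs[pairs[, 1] > 0, , drop = FALSE])
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  expect_equal(unname(sp$adjacency), unname(pairs))
})
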