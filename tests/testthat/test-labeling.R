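test_that("Butterworth similarity matches its closed form", {
  p <- labeling_params(eta = 5, n = 4)
  expect_equal(butterworth_similarity(100, 100, p), 1)
  expect_equal(butterworth_similarity(100, 105, p), 0.5)
  expect_equal(butterworth_similarity(100, 95, p), 0.5)  # symmetric
  expect_equal(butterworth_similarity(100, 110, p), 1 / 17)
  # strictly decreasing in the difference; steeper for larger order
  d <- seq(0, 30, by = 0.5)
  s4 <- butterworth_similarity(100, 100 + d, p)
  expect_true(all(diff(s4) < 0))
  s8 <- butterworth_similarity(100, 100 + d, labeling_params(eta = 5, n = 8))
  expect_true(all(s8[d > 5] < s4[d > 5]))
  expect_error(labeling_params(n = 3), "even")
})

test_that("initial labels split regions into confident and fuzzy sets", {
  sp <- chain_map(c(60, 130, 190))
  U <- rbind(c(0.9, 0.05, 0.05), c(0.4, 0.35, 0.25), c(0.1, 0.1, 0.8))
  d <- initial_labels(sp, mock_fcm(U), labeling_params(T_c = 0.7))
  expect_equal(d$region_class, c(1L, NA, 3L))
  expect_equal(d$provenance, c("confident", "fuzzy", "confident"))
  # T_c = 0 disables the fuzzy set: pure argmax labeling
  d0 <- initial_labels(sp, mock_fcm(U), labeling_params(T_c = 0))
  expect_equal(d0$region_class, c(1L, 1L, 3L))
  # argmax ties break to the lower class index
  dt <- initial_labels(chain_map(100), mock_fcm(rbind(c(0.5, 0.5, 0))),
                       labeling_params(T_c = 0.3))
  expect_equal(dt$region_class, 1L)
})

test_that("a fuzzy region adopts a similar labeled neighbour in one sweep", {
  sp <- chain_map(c(100, 105))  # difference eta/2 with eta = 10
  U <- rbind(c(0.95, 0.03, 0.02), c(0.34, 0.33, 0.33))
  prm <- labeling_params(eta = 10, n = 4, T_c = 0.7, T_s = 0.5)
  d <- initial_labels(sp, mock_fcm(U), prm)
  out <- broadcast_labels(d, sp, mock_fcm(U), prm)
  expect_equal(out$region_class, c(1L, 1L))
  expect_equal(out$provenance[2], "broadcast-1")
})

test_that("dissimilar fuzzy regions fall back to argmax membership", {
  sp <- chain_map(c(100, 200))  # far beyond eta: similarity << T_s
  U <- rbind(c(0.95, 0.03, 0.02), c(0.2, 0.45, 0.35))
  prm <- labeling_params(eta = 10, T_c = 0.7, T_s = 0.5, max_broadcast_iters = 3)
  out <- broadcast_labels(initial_labels(sp, mock_fcm(U), prm), sp, mock_fcm(U), prm)
  expect_equal(out$region_class[2], 2L)
  expect_equal(out$provenance[2], "fallback")
})

test_that("labels propagate one hop per frozen sweep along a fuzzy chain", {
  sp <- chain_map(c(150, 150, 150, 150))
  U <- rbind(c(0.9, 0.05, 0.05),
             c(0.4, 0.3, 0.3), c(0.4, 0.3, 0.3), c(0.4, 0.3, 0.3))
  prm <- labeling_params(T_c = 0.7, T_s = 0.5)
  out <- broadcast_labels(initial_labels(sp, mock_fcm(U), prm), sp, mock_fcm(U), prm)
  expect_equal(out$region_class, rep(1L, 4))
  expect_equal(out$provenance, c("confident", "broadcast-1", "broadcast-2", "broadcast-3"))
})

test_that("broadcast never relabels a confident region", {
  sp <- chain_map(c(100, 101, 102))
  U <- rbind(c(0.95, 0.03, 0.02), c(0.3, 0.4, 0.3), c(0.02, 0.03, 0.95))
  prm <- labeling_params(T_c = 0.7, T_s = 0.5)
  d <- initial_labels(sp, mock_fcm(U), prm)
  out <- broadcast_labels(d, sp, mock_fcm(U), prm)
  expect_equal(out$region_class[c(1, 3)], c(1L, 3L))
  expect_equal(out$provenance[c(1, 3)], c("confident", "confident"))
})

test_that("merging joins same-class neighbours and is idempotent", {
  sp <- chain_map(c(60, 62, 190, 188))
  labeled <- list(region_class = c(1L, 1L, 3L, 3L),
                  provenance = rep("confident", 4))
  seg <- merge_regions(labeled, sp)
  expect_equal(max(seg$merged_labels), 2L)  # two merged components
  seg2 <- merge_regions(labeled, sp)
  expect_identical(seg2$merged_labels, seg$merged_labels)
  # alternating classes: nothing merges
  lab_alt <- list(region_class = c(1L, 2L, 1L, 2L), provenance = rep("confident", 4))
  expect_equal(max(merge_regions(lab_alt, sp)$merged_labels), 4L)
  expect_error(merge_regions(list(region_class = c(1L, NA, 1L, 1L)), sp), "classified")
})

test_that("the final class map is invariant to region-id permutation", {
  p <- small_phantom(size = 48, noise = 3, gs = 2L)
  sp <- evolve_turbopixels(p$image, turbopixel_params(n_seeds = 9))
  fg <- sp$stats$id[sp$stats$mean >= 32]
  fcm <- fcm_cluster(sp$stats$mean[fg], fcm_params())
  prm <- labeling_params()
  seg <- merge_regions(broadcast_labels(
    initial_labels(sp, fcm, prm, fg), sp, fcm, prm, fg), sp)

  perm <- rev(seq_len(sp$K))
  lab2 <- matrix(perm[sp$labels], nrow(sp$labels), ncol(sp$labels))
  sp2 <- superpixel_map(lab2, p$image$pixels)
  fg2 <- sp2$stats$id[sp2$stats$mean >= 32]
  fcm2 <- fcm_cluster(sp2$stats$mean[fg2], fcm_params())
  seg2 <- merge_regions(broadcast_labels(
    initial_labels(sp2, fcm2, prm, fg2), sp2, fcm2, prm, fg2), sp2)
  expect_identical(seg2$class_map, seg$class_map)
})

test_that("provenance sidecar records one entry per region", {
  sp <- chain_map(c(60, 130, 190))
  labeled <- list(region_class = c(1L, 2L, 3L), provenance = rep("confident", 3))
  seg <- merge_regions(labeled, sp)
  f <- withr::local_tempfile(fileext = ".json")
  write_provenance(seg, f)
  rec <- jsonlite::read_json(f)
  expect_length(rec, 3L)
  expect_equal(rec[[2]]$class, "gray")
})
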