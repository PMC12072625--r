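sp0 <- c(0.8, 0.8, 4.4)

test_that("local contrast is zero on a flat image and signed correctly", {
  vol <- array(100, c(7, 7, 5))
  mask <- array(TRUE, c(7, 7, 5))
  expect_true(all(local_contrast(vol, mask) == 0))

  # single hot voxel: contrast = 160 - mean of 26 neighbors at 100 = 60
  vol[4, 4, 3] <- 160
  lc <- local_contrast(vol, mask)
  expect_equal(lc[4, 4, 3], 60)
  # its neighbors see a raised mean, hence negative contrast
  expect_lt(lc[3, 4, 3], 0)

  # dimmer-than-surroundings voxel is negative, never segmented
  vol2 <- array(100, c(7, 7, 5))
  vol2[4, 4, 3] <- 40
  expect_lt(local_contrast(vol2, mask)[4, 4, 3], 0)
  seg <- segment_pvs(vol2, mask, array(FALSE, dim(vol2)), sp0,
                     segmentation_config(uniformize = FALSE))
  expect_false(any(seg))
})

test_that("local contrast truncates the neighborhood at volume borders", {
  vol <- array(100, c(5, 5, 3))
  vol[1, 1, 1] <- 170
  mask <- array(TRUE, dim(vol))
  # corner voxel has 7 in-volume neighbors, all at 100
  expect_equal(local_contrast(vol, mask)[1, 1, 1], 70)
})

test_that("the in-plane kernel ignores adjacent slices", {
  vol <- array(100, c(7, 7, 5))
  vol[4, 4, 2] <- 150  # hot voxel in the slice below
  mask <- array(TRUE, dim(vol))
  lc2d <- local_contrast(vol, mask, kernel = "inplane8")
  lc3d <- local_contrast(vol, mask, kernel = "3d26")
  expect_equal(lc2d[4, 4, 3], 0)   # not a neighbor in-plane
  expect_lt(lc3d[4, 4, 3], 0)      # but it is in 3D
})

test_that("uniformize is the identity on a flat image and removes bias", {
  dm <- c(48, 48, 12)
  mask <- array(TRUE, dm)
  flat <- array(100, dm)
  out <- uniformize(flat, mask, sp0)
  expect_lt(max(abs(out - flat) / flat), 1e-6)

  # constant times an analytically smooth field, recovered within 2%
  x <- (seq_len(dm[1]) - 0.5) * sp0[1]
  z <- (seq_len(dm[3]) - 0.5) * sp0[3]
  bias <- 1 + 0.2 * (0.7 * (2 * (outer(x, rep(1, dm[2])) /
                                   (dm[1] * sp0[1]) - 0.5)))
  field <- array(rep(bias, dm[3]), dm) *
    array(rep(1 + 0.06 * cos(pi * z / (dm[3] * sp0[3])), each = prod(dm[1:2])),
          dm)
  vol <- 100 * field
  rec <- uniformize(vol, mask, sp0)
  expect_lt(max(abs(rec[mask] - 100) / 100), 0.02)

  expect_error(uniformize(flat, array(FALSE, dm), sp0), "empty")
})

test_that("segmentation threshold is strictly greater-than", {
  dm <- c(9, 9, 5)
  vol <- array(100, dm)
  mask <- array(TRUE, dm)
  none <- array(FALSE, dm)
  cfg <- segmentation_config(uniformize = FALSE)
  # interior voxel at 160: contrast exactly 60 -> NOT a PVS
  vol[5, 5, 3] <- 160
  expect_false(any(segment_pvs(vol, mask, none, sp0, cfg)))
  # a hair above the threshold -> included
  vol[5, 5, 3] <- 160.001
  seg <- segment_pvs(vol, mask, none, sp0, cfg)
  expect_true(seg[5, 5, 3])
  expect_equal(sum(seg), 1)
})

test_that("segmentation rejects mismatched shapes and respects masks", {
  vol <- array(100, c(6, 6, 4))
  expect_error(segment_pvs(vol, array(TRUE, c(6, 6, 5)),
                           array(FALSE, c(6, 6, 4)), sp0),
               "shape")
  # supra-threshold voxel outside the masks is not segmented
  vol[3, 3, 2] <- 300
  mask <- array(TRUE, c(6, 6, 4))
  mask[3, 3, 2] <- FALSE
  seg <- segment_pvs(vol, mask, array(FALSE, c(6, 6, 4)), sp0,
                     segmentation_config(uniformize = FALSE))
  expect_false(seg[3, 3, 2])
})

test_that("raising the threshold never adds segmented voxels", {
  ph <- generate_phantom(n_pvs = 25, noise_sd = 10, contrast = 110, seed = 13)
  prev <- Inf
  for (thr in c(40, 60, 80, 100)) {
    n <- sum(segment_pvs(ph$t2, ph$wm_mask, ph$bg_mask, ph$spacing,
                         segmentation_config(diff_threshold = thr)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("corner contact joins clusters, a gap separates them", {
  m <- array(FALSE, c(5, 5, 3))
  m[2, 2, 1] <- TRUE
  m[3, 3, 2] <- TRUE  # shares only a corner
  cl <- cluster_pvs(m)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$volume_voxels, 2)

  m2 <- array(FALSE, c(5, 5, 3))
  m2[2, 2, 2] <- TRUE
  m2[2, 4, 2] <- TRUE  # one empty voxel between
  expect_equal(nrow(cluster_pvs(m2)), 2)

  empty <- cluster_pvs(array(FALSE, c(4, 4, 2)))
  expect_equal(nrow(empty), 0)
})

test_that("clustering matches the graph-components oracle on random masks", {
  withr::local_seed(101)
  for (i in 1:20) {
    m <- random_small_mask()
    cl <- cluster_pvs(m)
    oracle <- oracle_components26(m)
    expect_equal(nrow(cl), if (length(oracle)) max(oracle) else 0)
    expect_equal(sum(cl$volume_voxels), sum(m))
    if (nrow(cl) > 0) {
      expect_equal(sort(table(oracle), decreasing = TRUE),
                   sort(table(rep(cl$cluster_id, cl$volume_voxels)),
                        decreasing = TRUE),
                   ignore_attr = TRUE)
    }
  }
})

test_that("diameter follows the max-over-slices equivalent-circle rule", {
  single <- matrix(c(3, 3, 2), nrow = 1)
  expect_equal(measure_diameter(single, sp0), 2 * sqrt(0.8 * 0.8 / pi))

  square4 <- rbind(c(3, 3, 2), c(4, 3, 2), c(3, 4, 2), c(4, 4, 2))
  expect_equal(measure_diameter(square4, sp0),
               2 * measure_diameter(single, sp0))

  two_slice <- rbind(c(3, 3, 1), c(3, 3, 2), c(4, 3, 2), c(3, 4, 2))
  expect_equal(measure_diameter(two_slice, sp0),
               2 * sqrt(3 * 0.8 * 0.8 / pi))

  expect_error(measure_diameter(matrix(numeric(0), ncol = 3), sp0), "empty")
})

test_that("diameter is invariant under in-plane translation and rotation", {
  withr::local_seed(5)
  base <- unique(cbind(sample(3:8, 12, TRUE), sample(3:8, 12, TRUE),
                       sample(1:3, 12, TRUE)))
  d0 <- measure_diameter(base, sp0)
  shifted <- base + matrix(rep(c(5, -2, 0), each = nrow(base)), ncol = 3)
  expect_equal(measure_diameter(shifted, sp0), d0)
  # 90-degree in-plane rotation: (x, y) -> (-y, x)
  rotated <- cbind(-base[, 2], base[, 1], base[, 3])
  expect_equal(measure_diameter(rotated, sp0), d0)
})

test_that("region assignment is majority with smallest-id tie-break", {
  labels <- array(0L, c(6, 6, 3))
  labels[1:3, , ] <- 5L
  labels[4:6, , ] <- 6L
  inside5 <- rbind(c(1, 1, 1), c(2, 2, 1))
  expect_equal(assign_region(inside5, labels), 5L)
  majority <- rbind(c(2, 2, 1), c(3, 2, 1), c(3, 3, 1), c(4, 2, 1))
  expect_equal(assign_region(majority, labels), 5L)
  tie <- rbind(c(3, 2, 1), c(3, 3, 1), c(4, 2, 1), c(4, 3, 1))
  expect_equal(assign_region(tie, labels), 5L)
  bg_only <- matrix(c(1, 1, 1), nrow = 1)
  labels_bg <- array(0L, c(3, 3, 2))
  expect_true(is.na(assign_region(bg_only, labels_bg)))
})

test_that("noiseless phantoms are recovered voxel-for-voxel", {
  ph <- generate_phantom(n_pvs = 20, noise_sd = 0, contrast = 120, seed = 31)
  mask <- segment_pvs(ph$t2, ph$wm_mask, ph$bg_mask, ph$spacing)
  truth_mask <- array(FALSE, dim(ph$t2))
  for (v in ph$truth$voxels) truth_mask[v] <- TRUE
  expect_identical(which(mask), which(truth_mask))
  expect_equal(nrow(cluster_pvs(mask)), 20)
})
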