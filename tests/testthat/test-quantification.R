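# Small constructed fixtures: a label map whose region voxel counts are easy
# to reason about, and hand-built cluster tables.
make_label_map <- function(reg) {
  labels <- array(0L, c(10, 10, 4))
  ids <- reg$label_id
  # give each region a run of voxels, round-robin over the flat array
  flat <- rep(ids, length.out = 300)
  labels[seq_along(flat)] <- flat
  labels
}

fake_cluster <- function(label, volume, diameter) {
  tibble::tibble(region_label = label, volume_voxels = volume,
                 diameter_mm = diameter)
}

test_that("an empty cluster set yields all-zero metrics and 288 data points", {
  reg <- build_registry("strict_72")
  labels <- make_label_map(reg)
  empty <- fake_cluster(integer(0), integer(0), numeric(0))
  rm <- quantify_regions(empty, labels, reg)
  expect_equal(nrow(rm), 72)
  expect_true(all(rm$pvs_count == 0))
  expect_true(all(rm$pvs_volume_voxels == 0))
  expect_true(all(rm$pvs_diameter_mm == 0))
  expect_true(all(rm$volume_fraction == 0))
  # 4 variables per region (count, volume, diameter, WM volume)
  expect_equal(nrow(rm) * 4, 288)
})

test_that("region metrics aggregate constructed clusters correctly", {
  reg <- build_registry("strict_72")
  labels <- make_label_map(reg)
  cl <- fake_cluster(c(1L, 1L, 1L, 2L), c(2L, 3L, 5L, 4L),
                     c(1.0, 2.0, 3.0, 1.5))
  rm <- quantify_regions(cl, labels, reg)
  r1 <- rm[rm$label_id == 1, ]
  expect_equal(r1$pvs_count, 3L)
  expect_equal(r1$pvs_volume_voxels, 10L)
  expect_equal(r1$pvs_diameter_mm, 2.0)
  expect_equal(r1$volume_fraction, 10 / r1$region_voxels)
  expect_equal(r1$count_fraction, 3 / r1$region_voxels)
  expect_true(all(rm$pvs_volume_voxels >= rm$pvs_count))
})

test_that("clusters on unknown labels or background are handled", {
  reg <- build_registry("strict_72")
  labels <- make_label_map(reg)
  expect_error(quantify_regions(fake_cluster(999L, 1L, 1), labels, reg),
               "999")
  expect_message(
    rm <- quantify_regions(fake_cluster(NA_integer_, 3L, 1), labels, reg),
    "background"
  )
  expect_true(all(rm$pvs_count == 0))
})

test_that("segmented voxels are conserved through region roll-up", {
  ph <- generate_phantom(n_pvs = 30, noise_sd = 0, contrast = 120, seed = 17)
  mask <- segment_pvs(ph$t2, ph$wm_mask, ph$bg_mask, ph$spacing)
  cl <- annotate_clusters(cluster_pvs(mask), ph$labels, ph$spacing)
  rm <- quantify_regions(cl, ph$labels, ph$registry)
  assigned <- cl[!is.na(cl$region_label), ]
  expect_equal(sum(rm$pvs_volume_voxels), sum(assigned$volume_voxels))
  expect_equal(sum(rm$pvs_count), nrow(assigned))
})

test_that("volume fraction is invariant under uniform upsampling", {
  reg <- build_registry("strict_72")
  labels <- make_label_map(reg)
  cl <- fake_cluster(c(1L, 2L), c(4L, 6L), c(1, 1))
  rm1 <- quantify_regions(cl, labels, reg)
  # upsample 2x in-plane: region voxel counts and cluster volumes scale by 4
  labels_up <- labels[rep(1:10, each = 2), rep(1:10, each = 2), ]
  cl_up <- fake_cluster(c(1L, 2L), c(16L, 24L), c(1, 1))
  rm2 <- quantify_regions(cl_up, labels_up, reg)
  expect_equal(rm2$volume_fraction, rm1$volume_fraction)
})

test_that("network aggregation sums members and weights diameters by count", {
  reg <- build_registry("analysis")
  labels <- make_label_map(reg)
  zero <- quantify_regions(fake_cluster(integer(0), integer(0), numeric(0)),
                           labels, reg)
  nets <- aggregate_networks(zero, reg)
  expect_equal(nrow(nets), 6)
  expect_true(all(nets$pvs_count == 0))

  # single cluster in the left precuneus appears in the left DMN only
  prec <- reg$label_id[reg$name == "precuneus" & reg$hemisphere == "left"]
  rm <- quantify_regions(fake_cluster(prec, 5L, 1.2), labels, reg)
  nets <- aggregate_networks(rm, reg)
  hit <- nets[nets$pvs_count > 0, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$network, "DMN")
  expect_equal(hit$side, "left")
  expect_equal(hit$pvs_volume_voxels, 5)

  # thalamus belongs to no analyzed network
  thal <- reg$label_id[reg$name == "thalamus" & reg$hemisphere == "right"]
  rm_thal <- quantify_regions(fake_cluster(thal, 9L, 2), labels, reg)
  expect_true(all(aggregate_networks(rm_thal, reg)$pvs_count == 0))

  # count-weighted diameter: caudate (CEN_FPN) with 3 clusters of mean 2.0
  # and rostral middle frontal with 1 cluster of 4.0 -> (3*2 + 1*4) / 4
  caud <- reg$label_id[reg$name == "caudate" & reg$hemisphere == "left"]
  rmf <- reg$label_id[reg$name == "rostral_middle_frontal" &
                        reg$hemisphere == "left"]
  cl2 <- fake_cluster(c(caud, caud, caud, rmf), c(1L, 1L, 1L, 1L),
                      c(1.5, 2.0, 2.5, 4.0))
  nets2 <- aggregate_networks(quantify_regions(cl2, labels, reg), reg)
  cen_left <- nets2[nets2$network == "CEN_FPN" & nets2$side == "left", ]
  expect_equal(cen_left$pvs_diameter_mm, (3 * 2 + 1 * 4) / 4)

  # incomplete region coverage is an error
  expect_error(aggregate_networks(rm[-1, ], reg), "cover")
})

test_that("the visual rating bins partition counts with the printed edges", {
  expect_equal(potter_score(c(0, 1, 10, 11, 20, 21, 40, 41)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L))
  scores <- potter_score(0:60)
  expect_true(all(diff(scores) >= 0))       # non-decreasing
  expect_equal(sort(unique(scores)), 0:4)   # no gaps
  expect_error(potter_score(-1), "non-negative")
  expect_error(potter_score(2.5), "whole")
})

test_that("visual-quantitative correlation behaves like Spearman should", {
  counts <- c(3, 15, 30, 50)  # one count per visual bin
  res <- compare_visual_vs_quantitative(counts, potter_score(counts))
  expect_equal(res$rho, 1)

  rev <- compare_visual_vs_quantitative(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev$rho, -1)

  x <- c(1, 2, 2, 4, 7, 7, 9)
  y <- c(2, 1, 4, 4, 6, 8, 8)
  res2 <- compare_visual_vs_quantitative(x, y)
  expect_equal(res2$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)

  expect_error(compare_visual_vs_quantitative(c(1, 1, 1), c(1, 2, 3)),
               "constant")
  expect_error(compare_visual_vs_quantitative(1:2, 1:2), "at least 3")
})

test_that("subject-level quantification normalizes by WM volume", {
  ph <- generate_phantom(n_pvs = 15, noise_sd = 0, contrast = 120, seed = 23)
  mask <- segment_pvs(ph$t2, ph$wm_mask, ph$bg_mask, ph$spacing)
  cl <- annotate_clusters(cluster_pvs(mask), ph$labels, ph$spacing)
  q <- quantify_subject(mask, cl, ph$labels, ph$wm_mask, ph$registry)
  expect_equal(q$wm_volume_voxels, sum(ph$wm_mask))
  expect_equal(q$wm_normalized_pvs_volume,
               sum(mask & ph$wm_mask) / sum(ph$wm_mask))
  # invariant to a global intensity rescaling that leaves every local
  # contrast on the same side of the threshold: the same voxels segment, so
  # the WM-normalized volume is unchanged
  mask2 <- segment_pvs(ph$t2 * 1.25, ph$wm_mask, ph$bg_mask, ph$spacing)
  expect_identical(which(mask2), which(mask))
  cl2 <- annotate_clusters(cluster_pvs(mask2), ph$labels, ph$spacing)
  q2 <- quantify_subject(mask2, cl2, ph$labels, ph$wm_mask, ph$registry)
  expect_equal(q2$wm_normalized_pvs_volume, q$wm_normalized_pvs_volume)
})
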