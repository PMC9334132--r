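test_that("z-map standardization matches hand-computed mean/sd", {
  v <- volume(array(c(1, 2, 3, 4, 5), dim = c(5, 1, 1)))
  inc <- array(TRUE, c(5, 1, 1))
  zp <- zscore_map(v, inc, sd_type = "population")
  expect_equal(as.numeric(zp$values),
               (1:5 - 3) / sqrt(mean((1:5 - 3)^2)), tolerance = 1e-12)
  expect_equal(as.numeric(zp$values)[1], -1.4142, tolerance = 1e-4)
  zs <- zscore_map(v, inc, sd_type = "sample")
  expect_equal(as.numeric(zs$values),
               c(-1.2649, -0.6325, 0, 0.6325, 1.2649), tolerance = 1e-4)
  # standardization identity on arbitrary data
  set.seed(31)
  a <- array(rnorm(9 * 9 * 9, 5, 3), c(9, 9, 9))
  inc2 <- array(runif(9^3) > 0.4, c(9, 9, 9))
  z <- zscore_map(volume(a), inc2)
  expect_equal(mean(z$values[inc2]), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(z$values[inc2]^2)), 1, tolerance = 1e-6)
  # constant difference map is degenerate
  expect_error(zscore_map(volume(array(7, c(4, 4, 4))), array(TRUE, c(4, 4, 4))),
               class = "perfusym_degenerate_map")
})

test_that("cluster extent rule keeps 125 voxels and drops 124", {
  z <- array(0, c(11, 11, 11))
  z[3:7, 3:7, 3:7] <- 3  # 5x5x5 = 125
  cs <- threshold_clusters(zmap_from_array(z), 2, min_extent = 125)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$extent_vox, 125L)
  expect_equal(cs$peak_z, 3)
  z[3, 3, 3] <- 0        # 124
  cs2 <- threshold_clusters(zmap_from_array(z), 2, min_extent = 125)
  expect_equal(nrow(cs2), 0L)
  # all-subthreshold map
  cs3 <- threshold_clusters(zmap_from_array(array(0.5, c(6, 6, 6))), 2)
  expect_equal(nrow(cs3), 0L)
})

test_that("connected components match a brute-force flood-fill oracle", {
  # two blobs separated by a 2-voxel gap: distinct under 6-connectivity
  z <- array(0, c(12, 7, 7))
  z[2:4, 2:4, 2:4] <- 3
  z[7:9, 2:4, 2:4] <- 3
  cs <- threshold_clusters(zmap_from_array(z), 2, min_extent = 1,
                           connectivity = 6)
  expect_equal(nrow(cs), 2L)
  expect_equal(sort(cs$extent_vox), c(27L, 27L))
  # random masks against the oracle, all three connectivities
  set.seed(32)
  for (conn in c(6L, 18L, 26L)) {
    m <- array(runif(10 * 9 * 8) > 0.7, c(10, 9, 8))
    got <- label_components(m, conn)
    want <- oracle_label_components(m, conn)
    expect_equal(got$n, want$n)
    expect_equal(sort(tabulate(got$labels[got$labels > 0], got$n)),
                 sort(tabulate(want$labels[want$labels > 0], want$n)))
  }
})

test_that("exclusion rules: distance, laterality, masks, empty lesion", {
  tpl <- test_template()
  lesion <- blob_mask(tpl, c(32, 12, 8), 6) & tpl$brain_mask
  z <- array(0, tpl$grid$dim)
  near_c <- c(34, -26, 10)   # right hemisphere, posterior to the lesion
  far_c <- c(20, -52, -18)   # right hemisphere, > 50 mm away
  mirror_c <- c(-32, 12, 8)  # contralateral mirror position
  z <- add_blob(z, tpl, near_c, 5, 4)
  z <- add_blob(z, tpl, far_c, 5, 3.5)
  z <- add_blob(z, tpl, mirror_c, 5, 3)
  zm <- zmap_from_array(z, include = tpl$brain_mask)
  zm$grid <- tpl$grid
  zm$mid_index <- tpl$mid_index
  cs <- threshold_clusters(zm, 2, min_extent = 1)
  expect_equal(nrow(cs), 3L)

  kept <- apply_exclusion_rules(cs, lesion, tpl, max_dist_mm = 50)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$peak_z, 4)
  # independent distance check: nearest surface-to-surface separation
  d_near <- sqrt(sum((near_c - c(32, 12, 8))^2)) - 6 - 5
  d_far <- sqrt(sum((far_c - c(32, 12, 8))^2)) - 6 - 5
  expect_lt(d_near, 50)
  expect_gt(d_far, 50)
  expect_equal(kept$min_lesion_distance_mm, d_near, tolerance = 0.2 * d_near)

  # empty lesion mask: distance/contralateral rules skipped with a warning
  expect_warning(
    all_kept <- apply_exclusion_rules(cs, array(FALSE, tpl$grid$dim), tpl),
    "empty lesion")
  expect_equal(nrow(all_kept), 3L)
  # empty input set stays empty
  empty <- threshold_clusters(zm, 10, min_extent = 1)
  expect_equal(nrow(apply_exclusion_rules(empty, lesion, tpl)), 0L)
})

test_that("clusters peaking in ventricles or outside the brain are removed", {
  tpl <- test_template()
  lesion <- blob_mask(tpl, c(32, 12, 8), 6) & tpl$brain_mask
  z <- array(0, tpl$grid$dim)
  z <- add_blob(z, tpl, c(0, -5, 0), 5, 5)      # inside ventricles
  zm <- zmap_from_array(z, include = array(TRUE, tpl$grid$dim))
  zm$grid <- tpl$grid; zm$mid_index <- tpl$mid_index
  cs <- threshold_clusters(zm, 2, min_extent = 1)
  expect_gte(nrow(cs), 1L)
  expect_equal(nrow(apply_exclusion_rules(cs, lesion, tpl)), 0L)
})

test_that("mirror-difference map is exactly antisymmetric", {
  tpl <- test_template()
  case <- simulate_case(phantom_spec(seed = 33), tpl)
  pz <- asymmetry_zmap(case$postictal, tpl)
  expect_identical(pz$diff$data, -flip_lr_array(pz$diff$data))
  # inclusion mask is symmetric by construction (stroke union its mirror)
  inc <- pz$z$include
  expect_identical(inc, flip_lr_array(inc))
  # every positive cluster has a mirror-image negative counterpart
  zneg <- pz$z; zneg$values <- -pz$z$values
  pos <- threshold_clusters(pz$z, 2, min_extent = 125)
  neg <- threshold_clusters(zneg, 2, min_extent = 125)
  expect_equal(nrow(pos), nrow(neg))
  expect_equal(sort(pos$extent_vox), sort(neg$extent_vox))
  expect_equal(sort(pos$centroid_x_mm), sort(-neg$centroid_x_mm),
               tolerance = 1e-9)
})

test_that("symmetric noiseless phantom yields a null, negative result", {
  tpl <- test_template()
  sp <- phantom_spec(seed = 1, lesion = list(present = FALSE),
                     island = list(present = FALSE),
                     noise = list(count_scale = 0))
  case <- simulate_case(sp, tpl)
  expect_identical(case$postictal$data, flip_lr_array(case$postictal$data))
  expect_warning(det <- detect_asymmetry(case$postictal, tpl),
                 "degenerate")
  expect_false(det$positive)
  expect_true(is.na(det$sd_level))
  expect_equal(det$laterality, "none")
  expect_equal(nrow(det$clusters), 0L)
})

test_that("a strong planted island is detected at 2.0 SD inside the island", {
  tpl <- test_template()
  case <- simulate_case(phantom_spec(seed = 34), tpl)
  det <- detect_asymmetry(case$postictal, tpl)
  expect_true(det$positive)
  expect_equal(det$sd_level, 2.0)
  expect_equal(det$laterality, case$truth$laterality)
  pk <- attr(det$clusters, "peak_vox")[1]
  expect_true(case$truth$island_mask[pk])
  expect_gt(det$clusters$peak_z[1], 3)
  # ground-truth lesion hint gives the same verdict
  det2 <- detect_asymmetry(case$postictal, tpl,
                           lesion_hint = case$truth$lesion_mask)
  expect_true(det2$positive)
  expect_equal(det2$sd_level, 2.0)
})

test_that("a calibrated weak island is caught only by the 1.5 SD fallback", {
  tpl <- test_template()
  sp <- phantom_spec(seed = 35, island = list(radius = 17))
  cal <- calibrate_island_amplitude(sp, tpl, target_z = 1.8)
  expect_lt(abs(cal$achieved_z - 1.8), 0.1)
  sp$island$amplitude <- cal$amplitude
  case <- simulate_case(sp, tpl)
  det <- detect_asymmetry(case$postictal, tpl)
  expect_true(det$positive)
  expect_equal(det$sd_level, 1.5)
  expect_lt(det$clusters$peak_z[1], 2.0)
  pk <- attr(det$clusters, "peak_vox")[1]
  expect_true(case$truth$island_mask[pk])
})

test_that("detection is deterministic for fixed inputs and parameters", {
  tpl <- test_template()
  case <- simulate_case(phantom_spec(seed = 36), tpl)
  d1 <- detect_asymmetry(case$postictal, tpl)
  d2 <- detect_asymmetry(case$postictal, tpl)
  expect_identical(d1$positive, d2$positive)
  expect_identical(d1$sd_level, d2$sd_level)
  expect_identical(as.data.frame(d1$clusters), as.data.frame(d2$clusters))
  expect_identical(d1$zmap$values, d2$zmap$values)
})

test_that("off-grid input is a contract error", {
  tpl <- test_template()
  expect_error(detect_asymmetry(volume(array(1, c(9, 9, 9))), tpl),
               "template grid")
})
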