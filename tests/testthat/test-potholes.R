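test_that("z-maps follow the deviation-score definition voxel by voxel", {
  cohort <- smallCohort()
  tpl <- buildTemplate(cohort$fa, cohort$mask)

  # a subject equal to the template mean scores 0 everywhere valid
  ghost <- FAVolume(tpl@mean, voxelSize(cohort$mask),
                    orientationTag(cohort$mask))
  zm0 <- computeZMap(ghost, cohort$mask, tpl)
  expect_true(all(zm0@z[validMask(zm0)] == 0))
  expect_true(all(is.na(zm0@z[!validMask(zm0)])))

  # arithmetic: (0.35 - 0.50) / 0.05 = -3 exactly
  expect_equal((0.35 - 0.50) / 0.05, -3)

  # random subject against the template agrees with a scalar per-voxel loop
  subj <- cohort$fa[[1]]
  zm <- computeZMap(subj, cohort$mask, tpl)
  idx <- which(validMask(zm))
  set.seed(2)
  for (lin in sample(idx, 50)) {
    zOracle <- (voxelValues(subj)[lin] - tpl@mean[lin]) / tpl@sd[lin]
    expect_equal(zm@z[lin], zOracle, tolerance = 1e-12)
  }
  # valid voxels are the template-valid / subject-mask intersection
  expect_true(all(validMask(zm) == (validMask(tpl) &
                                    voxelValues(cohort$mask))))
})

test_that("z-map computation rejects incompatible or disjoint inputs", {
  cohort <- smallCohort()
  tpl <- buildTemplate(cohort$fa, cohort$mask)
  wrong <- FAVolume(array(0.4, c(5, 5, 5)), voxelSize(cohort$mask),
                    orientationTag(cohort$mask))
  expect_error(computeZMap(wrong, cohort$mask, tpl), "mismatch")

  other <- voxelValues(cohort$mask)
  outside <- MaskVolume(!other, voxelSize(cohort$mask),
                        orientationTag(cohort$mask))
  expect_error(computeZMap(cohort$fa[[1]], outside, tpl),
               "empty valid intersection")
})

test_that("pothole detection recovers planted geometry", {
  shape <- c(12, 12, 12)
  z <- array(0, shape)
  expect_equal(nrow(detectPotholes(asZMap(z))), 0L)

  # one 3x3x3 block at z = -5
  z[3:5, 3:5, 3:5] <- -5
  cl <- detectPotholes(asZMap(z, voxelSize = c(2, 2, 3)), minSize = 10)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_voxels, 27L)
  expect_equal(cl$min_z, -5)
  expect_equal(cl$volume_mm3, 27 * 12)
  expect_equal(unname(c(cl$peak_i, cl$peak_j, cl$peak_k)), c(3, 3, 3))

  # 9-voxel blob: excluded at minSize 10, included at 9
  z2 <- array(0, shape)
  z2[2:4, 2:4, 2] <- -5
  expect_equal(nrow(detectPotholes(asZMap(z2), minSize = 10)), 0L)
  expect_equal(nrow(detectPotholes(asZMap(z2), minSize = 9)), 1L)

  # voxels exactly at the threshold are excluded (strict inequality)
  z3 <- array(0, shape)
  z3[2:4, 2:4, 2:4] <- -3
  expect_equal(nrow(detectPotholes(asZMap(z3), minSize = 1)), 0L)
  z3[2:4, 2:4, 2:4] <- -3 - 1e-9
  expect_equal(nrow(detectPotholes(asZMap(z3), minSize = 1)), 1L)
})

test_that("corner-touching blocks merge under 26- but not 6-connectivity", {
  z <- array(0, c(10, 10, 10))
  z[2:3, 2:3, 2:3] <- -5
  z[4:5, 4:5, 4:5] <- -5
  zm <- asZMap(z)
  expect_equal(nrow(detectPotholes(zm, minSize = 1, connectivity = 26)), 1L)
  expect_equal(nrow(detectPotholes(zm, minSize = 1, connectivity = 6)), 2L)
  expect_equal(nrow(detectPotholes(zm, minSize = 1, connectivity = 18)), 2L)
  expect_error(detectPotholes(zm, connectivity = 10), "connectivity")
  expect_error(detectPotholes(zm, minSize = 0), "minSize")
})

test_that("component labeling matches the flood-fill oracle on random grids", {
  set.seed(7)
  for (rep in 1:25) {
    shape <- sample(5:12, 3, replace = TRUE)
    z <- array(ifelse(runif(prod(shape)) < 0.2, -5, 0), shape)
    for (conn in c(6, 18, 26)) {
      cl <- detectPotholes(asZMap(z), minSize = 1, connectivity = conn)
      oracle <- canonicalPartition(floodFillLabel(z < -3, conn))
      expect_identical(canonicalClusters(cl, shape), oracle)
    }
  }
})

test_that("cluster lists satisfy the partition invariants", {
  set.seed(19)
  shape <- c(14, 14, 14)
  z <- array(rnorm(prod(shape), -2, 1), shape)
  cl <- detectPotholes(asZMap(z), zThreshold = -3, minSize = 2)
  linAll <- unlist(lapply(cl$voxels, function(m)
    (m[, 3] - 1) * shape[1] * shape[2] + (m[, 2] - 1) * shape[1] + m[, 1]))
  # every reported voxel is sub-threshold; no voxel in two clusters
  expect_true(all(z[linAll] < -3))
  expect_equal(anyDuplicated(linAll), 0L)
  # union equals the size-filtered thresholded set
  lab <- floodFillLabel(z < -3, 26)
  parts <- canonicalPartition(lab)
  kept <- parts[vapply(parts, length, integer(1)) >= 2]
  expect_setequal(linAll, unlist(kept))
  # ordering is by descending size with deterministic tie-break
  expect_true(all(diff(cl$n_voxels) <= 0))
  expect_identical(cl$cluster_id, seq_len(nrow(cl)))
})

test_that("threshold and size monotonicity hold on random z-maps", {
  set.seed(23)
  for (rep in 1:5) {
    z <- array(rnorm(10^3, -1.5, 1), c(10, 10, 10))
    zm <- asZMap(z)
    nAt <- function(th) sum(z < th)
    expect_gte(nAt(-2), nAt(-3))
    sizes <- c(1, 2, 5, 10)
    counts <- vapply(sizes, function(s)
      nrow(detectPotholes(zm, minSize = s)), numeric(1))
    expect_true(all(diff(counts) <= 0))
    # relaxing the z threshold never loses sub-threshold voxels
    v3 <- sum(vapply(detectPotholes(zm, zThreshold = -3, minSize = 1)$voxels,
                     nrow, integer(1)))
    v2 <- sum(vapply(detectPotholes(zm, zThreshold = -2, minSize = 1)$voxels,
                     nrow, integer(1)))
    expect_gte(v2, v3)
  }
})

test_that("missing voxels never join a cluster and mm3 size filtering works", {
  shape <- c(8, 8, 8)
  z <- array(-5, shape)
  valid <- array(FALSE, shape)
  valid[2:4, 2:4, 2:4] <- TRUE          # 27 valid voxels, all sub-threshold
  zm <- asZMap(z, voxelSize = c(2, 2, 3), validMask = valid)
  cl <- detectPotholes(zm, minSize = 1)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_voxels, 27L)

  # 27 voxels x 12 mm3 = 324 mm3
  expect_equal(nrow(detectPotholes(zm, minSize = 324, sizeUnits = "mm3")), 1L)
  expect_equal(nrow(detectPotholes(zm, minSize = 325, sizeUnits = "mm3")), 0L)
  # at this voxel volume a 10 mm3 filter is sub-voxel, hence inert
  expect_equal(detectPotholes(zm, minSize = 10, sizeUnits = "mm3")$n_voxels,
               27L)
})

test_that("pothole summaries aggregate cluster tables correctly", {
  s0 <- summarizePotholes("s0", detectPotholes(asZMap(array(0, c(6, 6, 6)))))
  expect_equal(unlist(s0[, 2:4]), c(n_potholes = 0,
                                    total_pothole_volume_mm3 = 0,
                                    mean_cluster_volume_mm3 = 0))

  cl <- data.frame(cluster_id = 1:2, n_voxels = c(10L, 30L),
                   volume_mm3 = c(10, 30) * 12, min_z = c(-4, -5))
  s <- summarizePotholes("s1", cl)
  expect_equal(s$n_potholes, 2)
  expect_equal(s$total_pothole_volume_mm3, 480)
  expect_equal(s$mean_cluster_volume_mm3, 240)

  set.seed(3)
  for (rep in 1:5) {
    vols <- runif(sample(1:6, 1), 10, 500)
    cl <- data.frame(cluster_id = seq_along(vols),
                     n_voxels = seq_along(vols), volume_mm3 = vols,
                     min_z = -5)
    s <- summarizePotholes("x", cl)
    expect_equal(s$total_pothole_volume_mm3, sum(vols))
    expect_equal(s$mean_cluster_volume_mm3, mean(vols))
  }
})

test_that("prevalence maps count subjects, not clusters", {
  toy <- toyAtlas(c(12, 12, 12))
  shape <- c(12, 12, 12)
  mkClusters <- function(ijkList) {
    if (!length(ijkList))
      return(detectPotholes(asZMap(array(0, shape))))
    df <- data.frame(cluster_id = seq_along(ijkList),
                     n_voxels = vapply(ijkList, nrow, integer(1)),
                     volume_mm3 = vapply(ijkList, nrow, integer(1)),
                     min_z = -5)
    df$voxels <- ijkList
    df
  }
  labs <- voxelValues(toy$atlas)
  vox5 <- arrayInd(which(labs == 5L)[1:3], shape)
  empty <- mkClusters(list())
  with5 <- mkClusters(list(vox5))

  none <- prevalenceMap(rep(list(empty), 4), toy$atlas)
  expect_true(all(none$perLabel$percent == 0))
  expect_true(all(none$voxelPercent == 0))

  all5 <- prevalenceMap(rep(list(with5), 4), toy$atlas)
  expect_equal(all5$perLabel$percent[all5$perLabel$label == 5], 100)
  expect_true(all(all5$perLabel$percent[all5$perLabel$label != 5] == 0))

  # 7 of 20 subjects with potholes in region 5 -> 35%
  sets <- c(rep(list(with5), 7), rep(list(empty), 13))
  p <- prevalenceMap(sets, toy$atlas)
  expect_equal(p$perLabel$percent[p$perLabel$label == 5], 35)
  lin5 <- which(labs == 5L)[1:3]
  expect_true(all(p$voxelPercent[lin5] == 35))
})
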