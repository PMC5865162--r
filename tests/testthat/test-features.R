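test_that("volumetric features match hand counts and a brute-force oracle", {
  seg <- array(0L, dim = c(20, 20, 20))
  labs <- subregion_labels()
  seg[1:4, 1:5, 1:5] <- labs[["ED"]]    # 100 voxels
  seg[5:8, 1:5, 1:5] <- labs[["NC"]]    # 100 voxels
  seg[9:12, 1:5, 1:5] <- labs[["TU"]]   # 100 voxels
  brain <- array(FALSE, dim = c(20, 20, 20)); brain[1:10, 1:10, 1:10] <- TRUE
  v <- compute_volumetric_features(seg, brain)
  expect_equal(unname(v), c(0.1, 0.1, 0.1, 1 / 3, 1.0))

  seg[seg == labs[["ED"]]] <- 0L  # no edema: ratio 0, no error
  v2 <- compute_volumetric_features(seg, brain)
  expect_equal(unname(v2[c("ED_VOLUME", "ED_TO_WT_RATIO")]), c(0, 0))

  expect_error(compute_volumetric_features(seg, array(FALSE, dim(seg))),
               "empty")

  set.seed(2)
  for (i in 1:5) {
    seg <- array(sample(c(0L, labs), 8000, replace = TRUE), dim = c(20, 20, 20))
    brain <- array(TRUE, dim = c(20, 20, 20))
    v <- compute_volumetric_features(seg, brain)
    counts <- vapply(labs, function(l) sum(seg == l), numeric(1))
    expect_equal(unname(v[1:3]), unname(counts[c("ED", "NC", "TU")]) / 8000)
    expect_equal(unname(v[4]), unname(counts[["ED"]] / sum(counts)))
    expect_equal(unname(v[5]), unname(counts[["TU"]] / counts[["NC"]]))
  }
})

test_that("circularity follows the exposed-edge definition", {
  # axis-aligned square side a: area a^2, perimeter 4a -> pi/4
  sq <- matrix(FALSE, 30, 30); sq[5:14, 5:14] <- TRUE
  expect_equal(compute_circularity(sq), pi / 4)
  # single voxel: 4*pi/16
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(compute_circularity(one), pi / 4)
  # rasterized disk: the exposed-edge (taxicab) perimeter of a disk is 8r,
  # giving the analytic limit 4*pi*(pi r^2)/(8r)^2 = pi^2/16
  r <- 40
  xy <- expand.grid(x = -50:50, y = -50:50)
  disk <- matrix(xy$x^2 + xy$y^2 <= r^2, 101, 101)
  expect_equal(compute_circularity(disk), pi^2 / 16, tolerance = 0.03)
  expect_error(compute_circularity(matrix(FALSE, 3, 3)), "empty")
})

test_that("sphericity follows the exposed-face definition", {
  # cube side a: pi^(1/3) (6 a^3)^(2/3) / (6 a^2) = (pi/6)^(1/3)
  cube <- array(FALSE, dim = c(20, 20, 20)); cube[3:12, 3:12, 3:12] <- TRUE
  expect_equal(compute_sphericity(cube), (pi / 6)^(1 / 3))
  # rasterized ball: face counting overestimates the sphere surface by 3/2,
  # so the analytic limit is 2/3
  r <- 30
  g <- expand.grid(x = -35:35, y = -35:35, z = -35:35)
  ball <- array(g$x^2 + g$y^2 + g$z^2 <= r^2, dim = c(71, 71, 71))
  expect_equal(compute_sphericity(ball), 2 / 3, tolerance = 0.03)
  # translation invariance
  shifted <- array(FALSE, dim = c(20, 20, 20)); shifted[7:16, 5:14, 2:11] <- TRUE
  expect_equal(compute_sphericity(cube), compute_sphericity(shifted))
  expect_error(compute_sphericity(array(FALSE, dim = c(3, 3, 3))), "empty")
})

test_that("intensity statistics are first-order population moments", {
  vol <- array(0, dim = c(4, 4, 4)); msk <- array(FALSE, dim = c(4, 4, 4))
  msk[1, 1, 1:4] <- TRUE
  vol[1, 1, 1:4] <- c(1, 2, 3, 4)
  st <- compute_intensity_stats(vol, msk)
  expect_equal(unname(st), c(2.5, sqrt(1.25)))  # population SD ~ 1.118

  vol[msk] <- 7
  expect_equal(unname(compute_intensity_stats(vol, msk)), c(7, 0))

  set.seed(4)
  vol <- array(rnorm(64), dim = c(4, 4, 4))
  msk <- array(runif(64) < 0.5, dim = c(4, 4, 4))
  st <- compute_intensity_stats(vol, msk)
  v <- vol[msk]
  expect_equal(unname(st[1]), sum(v) / length(v))
  expect_equal(unname(st[2]), sqrt(sum((v - mean(v))^2) / length(v)))

  expect_true(all(is.na(compute_intensity_stats(vol, msk & FALSE))))
})

test_that("histogram features use five equal-width bins on [0, 1]", {
  vol <- array(0.5, dim = c(10, 10, 10))
  msk <- array(TRUE, dim = c(10, 10, 10))
  expect_equal(compute_histogram_features(vol, msk), c(0, 0, 100, 0, 0))

  grid_vals <- seq(0.0005, 0.9995, length.out = 1000)
  vol2 <- array(grid_vals, dim = c(10, 10, 10))
  h <- compute_histogram_features(vol2, msk)
  expect_equal(h, rep(20, 5), tolerance = 0.5 / 20)

  set.seed(6)
  vol3 <- array(runif(1000), dim = c(10, 10, 10))
  expect_equal(sum(compute_histogram_features(vol3, msk)), 100, tolerance = 1e-9)
  expect_true(all(is.na(compute_histogram_features(vol3, msk & FALSE))))
})

test_that("channel normalization clips at the 1st/99th percentile", {
  set.seed(7)
  vol <- array(rnorm(8000, 5, 2), dim = c(20, 20, 20))
  brain <- array(TRUE, dim = c(20, 20, 20))
  nv <- normalize_channel(vol, brain)
  expect_true(all(nv >= 0 & nv <= 1))
  q <- quantile(vol[brain], c(0.01, 0.99), names = FALSE)
  inner <- vol > q[1] & vol < q[2]
  expect_equal(nv[inner], (vol[inner] - q[1]) / (q[2] - q[1]))
})

test_that("GLCM measures handle degenerate and two-voxel regions exactly", {
  vol <- array(3, dim = c(4, 4, 4)); msk <- array(TRUE, dim = c(4, 4, 4))
  g <- compute_glcm_measures(vol, msk)
  expect_equal(unname(g[c("energy", "contrast", "entropy",
                          "dissimilarity", "homogeneity")]),
               c(1, 0, 0, 0, 1))
  expect_true(is.na(g[["correlation"]]))

  # two voxels with distinct values quantize to levels 0 and 31: the only
  # co-occurrence matrix has two symmetric cells
  vol2 <- array(c(0, 1), dim = c(2, 1, 1))
  msk2 <- array(TRUE, dim = c(2, 1, 1))
  g2 <- compute_glcm_measures(vol2, msk2)
  expect_equal(g2[["contrast"]], 31^2)
  expect_equal(g2[["energy"]], 0.5)
  expect_equal(g2[["entropy"]], log(2))
  expect_equal(g2[["correlation"]], -1)
  expect_equal(g2[["dissimilarity"]], 31)
  expect_equal(g2[["homogeneity"]], 1 / (1 + 31^2))

  expect_error(compute_glcm_measures(vol2, msk2 & c(TRUE, FALSE)), ">= 2")
})

test_that("GLCM measures reproduce the pair-enumeration oracle", {
  set.seed(8)
  for (dims in list(c(6, 6, 6), c(10, 10, 10), c(12, 12, 12))) {
    vol <- array(rnorm(prod(dims)), dim = dims)
    msk <- array(runif(prod(dims)) < 0.6, dim = dims)
    if (sum(msk) < 2) next
    got <- compute_glcm_measures(vol, msk)
    want <- oracle_glcm(vol, msk)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("location features tally core voxels per atlas region", {
  atlas <- synthetic_atlas(c(32, 32, 32))
  labs <- subregion_labels()
  # core entirely inside one region
  seg <- array(0L, dim = c(32, 32, 32))
  frontal <- which(atlas == 1L)
  seg[frontal[1:40]] <- labs[["TU"]]
  seg[frontal[41:80]] <- labs[["NC"]]
  lf <- compute_location_features(seg, atlas)
  expect_equal(unname(lf["LOC_frontal"]), 100)
  expect_equal(sum(lf), 100)
  # split evenly across two regions
  temporal <- which(atlas == 2L)
  seg2 <- array(0L, dim = c(32, 32, 32))
  seg2[frontal[1:30]] <- labs[["TU"]]
  seg2[temporal[1:30]] <- labs[["NC"]]
  lf2 <- compute_location_features(seg2, atlas)
  expect_equal(unname(lf2[c("LOC_frontal", "LOC_temporal")]), c(50, 50))
  # random cores against the exhaustive tally oracle
  set.seed(9)
  for (i in 1:5) {
    seg3 <- array(0L, dim = c(32, 32, 32))
    pick <- sample(which(atlas > 0L), 200)
    seg3[pick] <- sample(c(labs[["TU"]], labs[["NC"]]), 200, replace = TRUE)
    core <- subregion_masks(seg3)$core
    expect_equal(unname(compute_location_features(seg3, atlas)),
                 oracle_region_tally(core, atlas))
  }
  expect_error(compute_location_features(array(0L, dim = c(32, 32, 32)), atlas),
               "empty")
})

test_that("the default catalog has the reconstructable family counts", {
  cat <- feature_catalog()
  counts <- table(cat$family)
  expect_equal(unname(counts[c("volumetric_shape", "intensity", "histogram",
                               "texture", "location", "growth")]),
               c(11L, 66L, 165L, 24L, 9L, 3L), ignore_attr = TRUE)
  expect_equal(nrow(cat), 278L)
  expect_false(anyDuplicated(cat$name) > 0)
  # exclusion list reproduces smaller historical catalog variants
  cat2 <- feature_catalog(exclude = c("ED_BINS_PSR_5", "NC_BINS_PSR_5"))
  expect_equal(sum(cat2$family == "histogram"), 163L)
})

test_that("feature extraction is deterministic, ordered and complete", {
  co <- small_cohort()
  tab <- extract_feature_table(co)
  expect_equal(dim(tab$X), c(6L, 278L))
  expect_equal(colnames(tab$X), feature_catalog()$name)
  expect_false(anyNA(tab$X))
  # histogram blocks sum to 100 per (region, channel)
  for (reg in c("ED", "NC", "TU")) for (ch in c("T1", "rCBV")) {
    cols <- paste(reg, "BINS", ch, 1:5, sep = "_")
    expect_equal(unname(rowSums(tab$X[, cols])), rep(100, 6), tolerance = 1e-6)
  }
  # duplicated subject gives an identical row
  studies <- co$studies[c(1, 1, 2)]
  tab2 <- extract_feature_table(studies, atlas = co$atlas)
  expect_equal(tab2$X[1, ], tab2$X[2, ])
  # a missing channel is reported with subject and channel name
  broken <- co$studies[[1]]
  broken$channels$rCBV <- NULL
  expect_error(extract_feature_table(list(broken), atlas = co$atlas),
               "S001.*rCBV")
  # growth features pass through from the clinical record
  expect_equal(unname(tab$X[, "GROWTH_DT"]),
               co$clinical$growth_dt)
})
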