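test_that("tSNR matches hand arithmetic and flags zero residual SD", {
  expect_equal(computeTsnr(c(98, 100, 102, 100, 100), detrendOrder = 0),
               100 / sqrt(2))
  expect_warning(v <- computeTsnr(seq(1, 10), detrendOrder = 1),
                 "flagged infinite")
  expect_true(is.infinite(v))
})

test_that("tSNR matches the polynomial-detrend oracle on random series", {
  set.seed(21)
  X <- matrix(rnorm(50 * 40, mean = 100), 50, 40)
  for (ord in 0:1)
    expect_equal(computeTsnr(X, ord), unname(oracleTsnr(X, ord)),
                 tolerance = 1e-10)
})

test_that("erosion of a solid cube keeps only the center voxel", {
  cube <- array(TRUE, dim = c(3, 3, 3))
  e <- erodeMask(cube)
  expect_equal(sum(e), 1)
  expect_true(e[2, 2, 2])
})

test_that("erosion of an empty mask is empty and warns", {
  expect_warning(e <- erodeMask(array(FALSE, dim = c(4, 4, 4))), "empty")
  expect_false(any(e))
})

test_that("erosion equals the 6-neighbour brute-force definition", {
  set.seed(22)
  for (i in 1:20) {
    m <- randomBlob(c(6, 7, 5), p = 0.7)
    got <- suppressWarnings(erodeMask(m))
    expect_identical(got, oracleErode(m))
    expect_true(all(m[got]))            # result is a subset of the input
  }
})

test_that("identity reslice in nearest-neighbour mode is exact", {
  set.seed(23)
  v <- array(runif(5 * 5 * 5), dim = c(5, 5, 5))
  m <- scalarMap(v, space = "native")
  out <- resliceToScanner(m, headPose(),
                          targetGrid = list(dims = c(5, 5, 5), spacing = 1),
                          method = "nearest")
  expect_identical(out@values, v)
  expect_equal(out@space, "scanner")
})

test_that("a pure translation moves a delta peak and conserves mass", {
  v <- array(0, dim = c(21, 21, 21))
  v[11, 11, 11] <- 1                      # voxel index 10 = world (0,0,0)
  m <- scalarMap(v, space = "native")
  out <- resliceToScanner(m, headPose(translations = c(10, 0, 0)),
                          targetGrid = list(dims = c(21, 21, 21),
                                            spacing = 1),
                          method = "nearest")
  expect_equal(sum(out@values, na.rm = TRUE), 1)
  expect_equal(which(out@values == 1, arr.ind = TRUE)[1, ],
               c(dim1 = 21, dim2 = 11, dim3 = 11))
})

test_that("reslice agrees with per-voxel brute-force inverse mapping", {
  set.seed(24)
  v <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
  m <- scalarMap(v, space = "native")
  pose <- headPose(rotations = c(0.1, -0.2, 0.15),
                   translations = c(1.5, -2, 0.5))
  tg <- list(dims = c(8, 8, 8), spacing = 2)
  out <- resliceToScanner(m, pose, targetGrid = tg)
  A <- poseAffine(pose)
  tgAff <- coilprint:::centeredGridAffine(c(8, 8, 8), 2)
  invMap <- solve(m@affine) %*% solve(A) %*% tgAff
  for (i in 0:7) for (j in 0:7) for (k in sample(0:7, 3)) {
    vox <- (invMap %*% c(i, j, k, 1))[1:3]
    expect_equal(out@values[i + 1, j + 1, k + 1], oracleTrilinear(v, vox),
                 tolerance = 1e-10)
  }
})

test_that("reslicing with a singular affine errors", {
  m <- scalarMap(array(1, dim = c(4, 4, 4)))
  expect_error(resliceToScanner(m, matrix(0, 4, 4)), "singular")
})

test_that("soft mean of identical maps is the identity with coverage 1", {
  set.seed(25)
  v <- array(runif(4^3), dim = c(4, 4, 4))
  v[1, , ] <- NA
  maps <- replicate(5, scalarMap(v, space = "scanner"), simplify = FALSE)
  sm <- softMean(maps)
  expect_equal(fieldValues(sm), v)
  expect_true(all(coverage(sm)[!is.na(v)] == 1))
  expect_true(all(coverage(sm)[is.na(v)] == 0))
})

test_that("soft mean of disjoint maps keeps each on its own support", {
  v1 <- array(NA_real_, dim = c(4, 4, 4)); v1[1:2, , ] <- 1
  v2 <- array(NA_real_, dim = c(4, 4, 4)); v2[3:4, , ] <- 3
  sm <- softMean(list(scalarMap(v1, space = "scanner"),
                      scalarMap(v2, space = "scanner")))
  expect_true(all(fieldValues(sm)[1:2, , ] == 1))
  expect_true(all(fieldValues(sm)[3:4, , ] == 3))
  expect_true(all(coverage(sm) == 0.5))
})

test_that("soft mean equals the per-voxel sum/count oracle", {
  set.seed(26)
  arrs <- replicate(20, {
    a <- array(runif(5^3), dim = c(5, 5, 5))
    a[randomBlob(c(5, 5, 5), 0.3)] <- NA
    a
  }, simplify = FALSE)
  sm <- softMean(lapply(arrs, scalarMap, space = "scanner"))
  o <- oracleSoftMean(arrs)
  expect_equal(fieldValues(sm), o$values, tolerance = 1e-12)
  expect_equal(coverage(sm), o$coverage, tolerance = 1e-12)
})

test_that("soft mean rejects grid mismatches", {
  expect_error(softMean(list(scalarMap(array(1, dim = c(4, 4, 4))),
                             scalarMap(array(1, dim = c(5, 5, 5))))),
               "identical grid")
})

test_that("a constant field predicts the same SNR for every ROI, any pose", {
  f <- constantCoilField(3.7)
  lab <- array(0L, dim = c(9, 9, 9))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[6:8, 6:8, 6:8] <- 2L
  atlas <- roiAtlas(lab)
  prof <- predictSnrGroup(f, atlas, headPose(rotations = c(0.2, 0.1, -0.1),
                                             translations = c(5, -3, 2)))
  expect_equal(as.numeric(prof), c(3.7, 3.7), tolerance = 1e-12)
  expect_equal(attr(prof, "provenance"), "group")
})

test_that("a single-voxel ROI equals the trilinear field sample", {
  f <- makeCoilField(gridShape = c(41, 41, 41), spacingMm = 4)
  lab <- array(0L, dim = c(5, 5, 5))
  lab[3, 3, 3] <- 1L                       # voxel at native (0, 0, 0)
  atlas <- roiAtlas(lab)
  pose <- headPose(rotations = c(0.05, 0, 0.1), translations = c(4, -18, 2))
  prof <- predictSnrGroup(f, atlas, pose)
  expect_equal(as.numeric(prof),
               as.numeric(sampleField(f, applyPose(pose, c(0, 0, 0)))),
               tolerance = 1e-12)
})

test_that("predictSnrGroup is invariant to atlas relabelling", {
  f <- makeCoilField(gridShape = c(41, 41, 41), spacingMm = 4)
  lab <- array(0L, dim = c(7, 7, 7))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[5:6, 5:6, 5:6] <- 2L
  pose <- headPose(translations = c(0, 10, 0))
  p1 <- predictSnrGroup(f, roiAtlas(lab), pose)
  relab <- lab
  relab[lab == 1L] <- 7L
  relab[lab == 2L] <- 4L
  tab <- data.frame(label = c(7L, 4L), roi = c(1L, 2L))
  p2 <- predictSnrGroup(f, roiAtlas(relab, labelTable = tab), pose)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-12)
})

test_that("ROIs posed outside coverage are reported by name", {
  f <- constantCoilField(1, gridShape = c(11, 11, 11), spacingMm = 1)
  lab <- array(0L, dim = c(5, 5, 5))
  lab[1, 1, 1] <- 1L
  lab[3, 3, 3] <- 2L
  expect_error(predictSnrGroup(f, roiAtlas(lab),
                               headPose(translations = c(20, 0, 0))),
               "outside field coverage")
})

test_that("reference-volume convention picks the floor midpoint", {
  poses <- matrix(rnorm(2300 * 6), 2300, 6)
  # protocol split of a 2300-volume session with a 154-volume gap
  p2 <- poseAtReferenceVolume(poses, c(1227L, 2300L))
  expect_equal(attr(p2, "volume"), 1763)
  expect_equal(translations(p2), poses[1764, 4:6])
  p1 <- poseAtReferenceVolume(poses, c(0L, 1073L))
  expect_equal(attr(p1, "volume"), 536)
  expect_equal(attr(poseAtReferenceVolume(poses, c(0L, 10L)), "volume"), 4)
  expect_equal(attr(poseAtReferenceVolume(poses, c(0L, 2300L)), "volume"),
               1149)
  expect_error(poseAtReferenceVolume(poses, c(2300L, 2400L)),
               "out of range")
})

test_that("brainmask centroid matches symmetry and the brute-force oracle", {
  m <- array(FALSE, dim = c(7, 7, 7))
  m[1, 1, 1] <- TRUE
  A <- diag(4)
  expect_equal(brainmaskCentroid(m, A), c(0, 0, 0))
  m2 <- array(FALSE, dim = c(11, 11, 11))
  m2[5:7, 5:7, 5:7] <- TRUE               # cube centered at voxel (5,5,5)
  A2 <- diag(c(2, 2, 2, 1))
  expect_equal(brainmaskCentroid(m2, A2), c(10, 10, 10))
  set.seed(27)
  blob <- randomBlob(c(5, 6, 4), 0.4)
  A3 <- coilprint:::centeredGridAffine(c(5, 6, 4), c(1.5, 2, 1))
  expect_equal(brainmaskCentroid(blob, A3), oracleCentroid(blob, A3),
               tolerance = 1e-10)
  expect_error(brainmaskCentroid(array(FALSE, dim = c(3, 3, 3)), diag(4)),
               "empty")
})
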