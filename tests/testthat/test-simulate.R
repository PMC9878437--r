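test_that("with a constant field and no state noise the sample connectome converges to the trait", {
  set.seed(61)
  trait <- structuredCorrelationMatrix(6, nNetworks = 2)
  sub <- new("SubjectSpec", traitConnectome = trait, headRadius = 25,
             covariates = list())
  f <- constantCoilField(1)
  s <- simulateSession(sub, headPose(), f, nVolumes = 4096, stateNoise = 0,
                       motionSpec = list(spikeRate = 0, spikeAmplitudeMm = 0),
                       seed = 62)
  M <- connectivityMatrix(computeConnectome(roiTimeseries(s)))
  expect_lt(max(abs(M - trait)), 0.05)
})

test_that("independent ROIs stay uncorrelated", {
  sub <- new("SubjectSpec", traitConnectome = diag(2), headRadius = 25,
             covariates = list())
  s <- simulateSession(sub, headPose(), constantCoilField(1),
                       nVolumes = 2048, stateNoise = 0, seed = 63)
  r <- cor(t(roiTimeseries(s)))[1, 2]
  expect_lt(abs(r), 3 / sqrt(2048))
})

test_that("a 20 mm pose shift changes tSNR by the planted field ratio", {
  f <- makeCoilField()
  set.seed(64)
  trait <- structuredCorrelationMatrix(30)
  sub <- new("SubjectSpec", traitConnectome = trait, headRadius = 28,
             covariates = list())
  p0 <- headPose()
  p1 <- headPose(translations = c(0, -20, 0))   # 20 mm toward the coil
  s0 <- simulateSession(sub, p0, f, nVolumes = 2048, seed = 65,
                        jitterScale = 0, stateNoise = 0)
  s1 <- simulateSession(sub, p1, f, nVolumes = 2048, seed = 65,
                        jitterScale = 0, stateNoise = 0)
  t0 <- computeTsnr(roiTimeseries(s0))
  t1 <- computeTsnr(roiTimeseries(s1))
  near <- which.min(s0@roiCenters[, 2])          # most posterior ROI
  fieldRatio <- sampleField(f, applyPose(p1, s0@roiCenters[near, , drop = FALSE])) /
    sampleField(f, applyPose(p0, s0@roiCenters[near, , drop = FALSE]))
  expect_equal(t1[near] / t0[near], as.numeric(fieldRatio), tolerance = 0.15)
})

test_that("simulated sessions are a pure function of the seed", {
  set.seed(66)
  sub <- new("SubjectSpec", traitConnectome = structuredCorrelationMatrix(10),
             headRadius = 25, covariates = list())
  f <- constantCoilField(1)
  a <- simulateSession(sub, headPose(), f, nVolumes = 128, seed = 67)
  b <- simulateSession(sub, headPose(), f, nVolumes = 128, seed = 67)
  expect_identical(roiTimeseries(a), roiTimeseries(b))
  expect_identical(poseMatrix(a), poseMatrix(b))
})

test_that("invalid traits and out-of-field poses are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)               # |rho| > 1, not PSD
  expect_error(new("SubjectSpec", traitConnectome = bad, headRadius = 25,
                   covariates = list()))
  sub <- new("SubjectSpec", traitConnectome = diag(3), headRadius = 25,
             covariates = list())
  small <- constantCoilField(1, gridShape = c(11, 11, 11), spacingMm = 1)
  expect_error(simulateSession(sub, headPose(translations = c(100, 0, 0)),
                               small, nVolumes = 64),
               "outside field coverage")
})

cohortSmallCfg <- function(...)
  cohortConfig(nRoi = 20, nVolumes = 64, ...)

test_that("cohort generation counts subjects, sessions and ledger entries", {
  cohort <- makeCohort(44, 2, cohortSmallCfg(), seed = 5)
  expect_length(cohort$sessions, 88)
  expect_length(cohort$ledger$subjects, 44)
  expect_length(cohort$ledger$basePoses, 44)
  expect_equal(nrow(cohort$ledger$covariates), 44)
  ids <- vapply(cohort$sessions, function(s) s@participantId, "")
  expect_equal(sort(unique(table(ids))), 2)
})

test_that("identical seeds give bit-identical cohorts and ledgers", {
  a <- makeCohort(4, 2, cohortSmallCfg(), seed = 9)
  b <- makeCohort(4, 2, cohortSmallCfg(), seed = 9)
  expect_identical(lapply(a$sessions, roiTimeseries),
                   lapply(b$sessions, roiTimeseries))
  expect_identical(a$ledger$trueSnr, b$ledger$trueSnr)
  expect_identical(a$ledger$covariates, b$ledger$covariates)
})

test_that("measured tSNR tracks the planted SNR across a cohort", {
  cohort <- makeCohort(6, 1, cohortConfig(nRoi = 30, nVolumes = 1024),
                       seed = 11)
  measured <- unlist(lapply(cohort$sessions, function(s)
    computeTsnr(roiTimeseries(s))))
  planted <- unlist(cohort$ledger$trueSnr)
  expect_gt(cor(measured, planted, method = "spearman"), 0.9)
})

test_that("zero repositioning and state noise equalize within- and across-session similarity", {
  cohort <- makeCohort(6, 2,
                       cohortConfig(nRoi = 50, nVolumes = 1500,
                                    stateNoise = 0, repositioning = "none",
                                    motionSpec = list(spikeRate = 0,
                                                      spikeAmplitudeMm = 0)),
                       seed = 13)
  splitConn <- lapply(cohort$sessions, function(s) {
    sp <- splitSession(s)
    lapply(sp, function(sg)
      edgeVector(computeConnectome(bandpass(sg))))
  })
  within <- vapply(seq(1, 12, by = 2), function(i)
    oracleSpearman(splitConn[[i]][[1]], splitConn[[i]][[2]]), 0)
  across <- vapply(seq(1, 12, by = 2), function(i)
    oracleSpearman(splitConn[[i]][[1]], splitConn[[i + 1]][[2]]), 0)
  expect_lt(abs(mean(within) - mean(across)), 0.05)
})

test_that("a null cohort identifies at chance", {
  # homogeneous field, no trait differences: across-session identification
  # should fall inside the 95% binomial band of chance (1/n)
  cohort <- makeCohort(10, 2,
                       cohortConfig(nRoi = 40, nVolumes = 700,
                                    individualWeight = 0,
                                    field = constantCoilField(1)),
                       seed = 17)
  an <- suppressWarnings(analyzeCohort(cohort))  # stability models degenerate here
  matches <- an$identification$acrossConn$matches
  expect_lte(matches, qbinom(0.975, 10, 1 / 10))
})
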