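test_that("framewise displacement handles constant and step poses", {
  poses <- matrix(0, 10, 6)
  expect_equal(framewiseDisplacement(poses)$perVolume, rep(0, 10))
  poses2 <- matrix(0, 5, 6)
  poses2[3:5, 4] <- 1                    # +1 mm x step at volume 3
  fwd <- framewiseDisplacement(poses2)
  expect_equal(fwd$perVolume, c(0, 0, 1, 0, 0))
  expect_equal(fwd$mean, 0.25)
})

test_that("framewise displacement matches the successive-difference oracle", {
  set.seed(51)
  poses <- apply(matrix(rnorm(60 * 6, sd = 0.1), 60, 6), 2, cumsum)
  for (radius in c(35, 50)) {
    fwd <- framewiseDisplacement(poses, radius)
    expect_equal(fwd$perVolume, oracleFwd(poses, radius), tolerance = 1e-12)
    expect_equal(fwd$mean, mean(oracleFwd(poses, radius)[-1]),
                 tolerance = 1e-12)
  }
})

test_that("a perfectly coupled single edge recovers slope 1", {
  # 3 participants, 2 ROIs -> 1 edge; connectivity equals the SNR product
  C <- matrix(c(-1, 0, 1), 3, 1)
  S <- rbind(c(1, 0.5), c(1, 1), c(1, 1.5))   # products 0.5, 1.0, 1.5
  fit <- edgewiseSnrFcRegression(C, S, nPermutations = 50)
  expect_equal(unname(fit$beta), 1, tolerance = 1e-12)
})

test_that("label-shuffled SNR profiles sit inside the permutation null", {
  set.seed(52)
  P <- 40; R <- 12
  S <- matrix(runif(P * R, 10, 40), P, R)
  C <- matrix(rnorm(P * R * (R - 1) / 2), P)
  fit <- edgewiseSnrFcRegression(C, S[sample(P), ], nPermutations = 400)
  expect_gt(fit$permutationP, 0.05)
  band <- quantile(fit$permutationNull, c(0.025, 0.975))
  expect_gt(fit$meanBeta, band[1])
  expect_lt(fit$meanBeta, band[2])
})

test_that("zero-variance regressors are skipped and counted", {
  set.seed(53)
  C <- matrix(rnorm(20 * 3), 20, 3)
  S <- cbind(rep(2, 20), runif(20), runif(20))   # ROI 1 constant
  # edges (1,2) and (1,3) have constant-free products; edge (2,3) varies
  S[, 1] <- 1
  fit <- edgewiseSnrFcRegression(C, S, nPermutations = 10)
  expect_equal(fit$nEdges + fit$nSkipped, 3)
  expect_equal(fit$nSkipped, 0)  # products with a constant factor still vary
  S2 <- matrix(1, 20, 3)
  fit2 <- edgewiseSnrFcRegression(C, S2, nPermutations = 10)
  expect_equal(fit2$nEdges, 0)
  expect_equal(fit2$nSkipped, 3)
})

test_that("identical segments make connectivity the sole predictor", {
  set.seed(54)
  P <- 30
  E10 <- 10 * (10 - 1) / 2
  C1 <- matrix(rnorm(P * E10), P, E10)
  S <- matrix(runif(P * 10, 20, 60), P, 10)   # independent noise profiles
  fit <- predictorComparison(C1, C1, S)
  expect_equal(unname(fit$betaFc), rep(1, E10), tolerance = 1e-10)
  expect_lt(max(abs(fit$betaSnr)), 1e-10)
})

test_that("orthonormal-regressor coefficients satisfy the variance bound", {
  set.seed(55)
  P <- 50; R <- 8
  S <- matrix(runif(P * R, 10, 50), P, R)
  C1 <- matrix(rnorm(P * R * (R - 1) / 2), P)
  C2 <- 0.5 * C1 + 0.5 * matrix(rnorm(P * ncol(C1)), P)
  fit <- predictorComparison(C1, C2, S)
  # R^2 <= 1 at every edge implies a bound on the standardized coefficients
  a <- colSums(coilprint:::zscoreCols(snrProductMatrix(S)) *
                 coilprint:::zscoreCols(C1)) / (P - 1)
  r2 <- fit$betaSnr^2 + fit$betaFc^2 + 2 * a * fit$betaSnr * fit$betaFc
  expect_lt(max(r2), 1 + 1e-8)
})

test_that("planted stability coefficients are recovered within 0.07", {
  set.seed(56)
  n <- 200
  snr <- rnorm(n, 30, 5)
  fwd <- rnorm(n, 0.3, 0.1)
  y <- 0.4 * coilprint:::zscore(snr) - 0.3 * coilprint:::zscore(fwd) +
    rnorm(n, 0, 0.2)
  fit <- stabilityRegression(y, data.frame(snr = snr, fwd = fwd),
                             model = "split_session")
  expect_lt(abs(fit$coefficients[["snr"]] - 0.4), 0.07)
  expect_lt(abs(fit$coefficients[["fwd"]] + 0.3), 0.07)
})

test_that("null coefficients stay inside the 95% null band", {
  set.seed(57)
  n <- 120
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rnorm(n, 0, 0.2)
  fit <- stabilityRegression(y, X, model = "any")
  se <- 0.2 / sqrt(n)
  expect_true(all(abs(fit$coefficients) < 3 * se))
})

test_that("an exact line is fit exactly", {
  y <- c(1, 2, 3)
  fit <- stabilityRegression(y, data.frame(x = c(10, 20, 30)), model = "any")
  expect_equal(unname(fit$coefficients), sd(c(10, 20, 30)) / 10,
               tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit$fit))), 1e-12)
})

test_that("rank-deficient designs error naming the collinear columns", {
  set.seed(58)
  n <- 40
  a <- rnorm(n)
  expect_error(stabilityRegression(rnorm(n),
                                   data.frame(a = a, b = 2 * a), "any"),
               "collinear")
  expect_error(stabilityRegression(rnorm(10),
                                   data.frame(a = rnorm(10)), "full_session"),
               "expects 5")
})

test_that("covariate correlation recovers exact and random relationships", {
  x <- c(1, 3, 5, 7, 9)
  expect_equal(covariateCorrelation(x, x)$r, 1)
  expect_equal(covariateCorrelation(x, -x)$r, -1)
  set.seed(59)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  got <- covariateCorrelation(a, b)
  expect_equal(got$r, cor(a, b), tolerance = 1e-10)
  expect_equal(got$ci, oracleFisherCi(a, b), tolerance = 1e-10)
  expect_error(covariateCorrelation(a, rep(1, 30)), "zero variance")
})

test_that("z-scoring is idempotent and fits are scale-invariant", {
  set.seed(60)
  x <- rnorm(25, 100, 7)
  z <- coilprint:::zscore(x)
  expect_equal(coilprint:::zscore(z), z, tolerance = 1e-12)
  y <- rnorm(25)
  f1 <- stabilityRegression(y, data.frame(a = x), "any")
  f2 <- stabilityRegression(y, data.frame(a = 1000 + 3 * x), "any")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})
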