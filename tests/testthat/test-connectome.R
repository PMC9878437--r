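test_that("protocol split: 2300 volumes with a 154-volume gap", {
  s <- makeTestSession(matrix(rnorm(2 * 2300), 2), tr = 0.392)
  sp <- splitSession(s, gapVolumes = 154)
  expect_equal(sp[[1]]@range, c(0L, 1073L))
  expect_equal(sp[[2]]@range, c(1227L, 2300L))
  expect_equal(ncol(sp[[1]]@data), 1073)
  expect_equal(ncol(sp[[2]]@data), 1073)
  # deriving the gap from 60 s at TR 0.392 rounds to 153 volumes
  sp2 <- splitSession(s, gapSeconds = 60)
  expect_equal(diff(sp2[[1]]@range) + diff(sp2[[2]]@range), 2300 - 153)
})

test_that("gap is centered; odd remainders favour the first segment", {
  s <- makeTestSession(matrix(rnorm(10), 1), tr = 1)
  sp <- splitSession(s, gapVolumes = 2, minSegment = 2)
  expect_equal(sp[[1]]@range, c(0L, 4L))
  expect_equal(sp[[2]]@range, c(6L, 10L))
  sp0 <- splitSession(s, gapVolumes = 0, minSegment = 2)
  expect_equal(sp0[[1]]@range, c(0L, 5L))
  expect_equal(sp0[[2]]@range, c(5L, 10L))
  sOdd <- makeTestSession(matrix(rnorm(11), 1), tr = 1)
  spo <- splitSession(sOdd, gapVolumes = 0, minSegment = 2)
  expect_equal(diff(spo[[1]]@range), 6)
  expect_equal(diff(spo[[2]]@range), 5)
})

test_that("segments never overlap and union plus gap is the session", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(150:400, 1)
    gap <- sample(0:20, 1)
    s <- makeTestSession(matrix(rnorm(n), 1), tr = 1)
    sp <- splitSession(s, gapVolumes = gap, minSegment = 8)
    expect_lte(sp[[1]]@range[2], sp[[2]]@range[1])
    expect_equal(sp[[2]]@range[1] - sp[[1]]@range[2], gap)
    expect_equal(diff(sp[[1]]@range) + diff(sp[[2]]@range) + gap, n)
  }
})

test_that("too-short sessions are rejected", {
  s <- makeTestSession(matrix(rnorm(100), 1), tr = 1)
  expect_error(splitSession(s, gapVolumes = 10), "too short")
})

test_that("bandpass preserves passband and attenuates stopband sinusoids", {
  tr <- 0.392
  t0 <- seq_len(2048) * tr
  inBand <- sin(2 * pi * 0.05 * t0)
  outBand <- sin(2 * pi * 0.5 * t0)
  Y <- bandpass(rbind(inBand, outBand), tr = tr)
  mid <- 500:1500                      # avoid filter edge effects
  ampIn <- max(abs(Y[1, mid]))
  ampOut <- max(abs(Y[2, mid]))
  expect_gt(ampIn, 0.95)
  expect_lt(ampOut, 0.1)
})

test_that("filtered white noise concentrates its power in the band", {
  set.seed(32)
  tr <- 0.392
  x <- matrix(rnorm(4096), 1)
  y <- bandpass(x, tr = tr)[1, ]
  # periodogram oracle
  n <- length(y)
  pw <- Mod(fft(y))^2 / n
  fr <- (seq_len(n) - 1) / (n * tr)
  fr <- pmin(fr, 1 / tr - fr)
  inBand <- fr >= 0.01 & fr <= 0.1
  expect_gt(sum(pw[inBand]) / sum(pw), 0.8)
})

test_that("invalid bands are rejected", {
  x <- matrix(rnorm(512), 1)
  expect_error(bandpass(x, lowHz = 0.01, highHz = 2, tr = 0.392), "invalid")
  expect_error(bandpass(x, lowHz = 0.2, highHz = 0.1, tr = 0.392), "invalid")
})

test_that("connectome edges behave as Pearson correlations", {
  x <- rnorm(100)
  X <- rbind(x, x, -x, rnorm(100))
  cn <- computeConnectome(X)
  M <- connectivityMatrix(cn)
  expect_equal(M[1, 2], 1)
  expect_equal(M[1, 3], -1)
  expect_equal(unname(diag(M)), rep(1, 4))
  expect_lt(max(abs(M - t(M))), 1e-12)
})

test_that("connectome matches the brute-force covariance oracle", {
  set.seed(33)
  X <- matrix(rnorm(5 * 100), 5)
  M <- connectivityMatrix(computeConnectome(X))
  expect_equal(M, oraclePearson(X), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("connectome is invariant to per-ROI affine rescaling", {
  set.seed(34)
  X <- matrix(rnorm(6 * 80), 6)
  scales <- runif(6, 0.5, 10)
  offsets <- rnorm(6, 100, 20)
  X2 <- X * scales + offsets
  expect_equal(connectivityMatrix(computeConnectome(X)),
               connectivityMatrix(computeConnectome(X2)),
               tolerance = 1e-12)
})

test_that("constant series flag their edges NA with a warning", {
  X <- rbind(rnorm(50), rep(2, 50), rnorm(50))
  expect_warning(cn <- computeConnectome(X), "constant")
  M <- connectivityMatrix(cn)
  expect_true(is.na(M[1, 2]) && is.na(M[2, 3]))
  expect_false(is.na(M[1, 3]))
  expect_equal(diag(M), rep(1, 3))
})

test_that("edge vectorization is the row-major upper triangle", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- 0.12; M[1, 3] <- 0.13; M[2, 3] <- 0.23
  M <- M + t(M); diag(M) <- 1
  cn <- new("Connectome", mat = M, roiIds = 1:3)
  expect_equal(edgeVector(cn), c(0.12, 0.13, 0.23))
})

test_that("QC removes exactly the planted deviant ROI (strict >10% rule)", {
  set.seed(35)
  mkSessions <- function(nOutlierSessions, drop = 5) {
    lapply(seq_len(10), function(k) {
      X <- matrix(rnorm(20 * 30, mean = 100, sd = 1), 20, 30)
      X <- X - rowMeans(X) + 100          # tight ROI means
      X[7, ] <- X[7, ] - c(0, drop)[(k <= nOutlierSessions) + 1]
      makeTestSession(X, id = sprintf("S%02d", k))
    })
  }
  qc3 <- qcRoiFilter(mkSessions(3))
  expect_identical(as.integer(qc3$removedRois), 7L)   # 3/10 > 10%
  qc1 <- qcRoiFilter(mkSessions(1))
  expect_length(qc1$removedRois, 0)                   # 1/10 = 10%, not >
})

test_that("identical ROI means produce no outliers (zero SD handled)", {
  sessions <- lapply(1:4, function(k)
    makeTestSession(matrix(5, 8, 20) + 0, id = sprintf("S%d", k)))
  qc <- qcRoiFilter(sessions)
  expect_length(qc$removedRois, 0)
  expect_false(any(qc$perSession))
})

test_that("QC removal is invariant to session order", {
  set.seed(36)
  sessions <- lapply(1:10, function(k) {
    X <- matrix(rnorm(15 * 25, 100), 15, 25)
    if (k <= 4) X[3, ] <- X[3, ] - 50
    makeTestSession(X, id = sprintf("S%02d", k))
  })
  qcA <- qcRoiFilter(sessions)
  qcB <- qcRoiFilter(rev(sessions))
  expect_identical(qcA$removedRois, qcB$removedRois)
})
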