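# Internal helpers shared across modules.

# Row-major upper-triangle (i < j) vectorization; the canonical edge order.
upperTriRowMajor <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}

# z-score with the unbiased (n-1) SD; zero-variance input yields NaN.
zscore <- function(x) (x - mean(x)) / sd(x)

# Column-wise z-score of a matrix.
zscoreCols <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  sweep(sweep(X, 2, mu, "-"), 2, s, "/")
}

# Derive a reproducible child seed (< 2^31) from a parent seed and a tag.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + k * 104729) %% 2147483629 + 1)
}

# Affine for a regular grid centered on the scanner origin:
# world = spacing * (index - (dim-1)/2), index 0-based.
centeredGridAffine <- function(dims, spacing) {
  spacing <- rep_len(spacing, 3L)
  A <- diag(4)
  diag(A)[1:3] <- spacing
  A[1:3, 4] <- -spacing * (dims - 1) / 2
  A
}

# Map world-mm points (n x 3) to continuous 0-based voxel coordinates.
worldToVoxel <- function(affine, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  inv <- solve(affine)
  h <- cbind(pts, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

# Map 0-based voxel coordinates (n x 3) to world mm.
voxelToWorld <- function(affine, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# Sample a 3-D array at continuous 0-based voxel coordinates.
# method "trilinear" (NA if any contributing corner is NA or outside) or
# "nearest" (NA outside). Returns numeric(n).
sampleGridVoxel <- function(values, vox, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(values)
  n <- nrow(vox)
  out <- rep(NA_real_, n)
  if (method == "nearest") {
    idx <- round(vox)
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    if (any(ok)) {
      lin <- idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3]) + 1
      out[ok] <- values[lin]
    }
    return(out)
  }
  f <- floor(vox)
  w <- vox - f
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 + (w[, 1] == 0) &
        f[, 2] >= 0 & f[, 2] <= d[2] - 2 + (w[, 2] == 0) &
        f[, 3] >= 0 & f[, 3] <= d[3] - 2 + (w[, 3] == 0)
  # points exactly on the far face: pull inside so the +1 corner exists
  for (a in 1:3) {
    hi <- f[, a] == d[a] - 1 & w[, a] == 0
    f[hi, a] <- d[a] - 2
    w[hi, a] <- 1
  }
  ok <- ok & f[, 1] >= 0 & f[, 2] >= 0 & f[, 3] >= 0
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE]
  wo <- w[ok, , drop = FALSE]
  acc <- rep(0, sum(ok))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
          (if (dy) wo[, 2] else 1 - wo[, 2]) *
          (if (dz) wo[, 3] else 1 - wo[, 3])
    lin <- (fo[, 1] + dx) + d[1] * ((fo[, 2] + dy) + d[2] * (fo[, 3] + dz)) + 1
    acc <- acc + wt * values[lin]
  }
  out[ok] <- acc
  out
}

# Sample a 3-D array at world-mm points through its affine.
sampleGridWorld <- function(values, affine, pts, method = "trilinear") {
  sampleGridVoxel(values, worldToVoxel(affine, pts), method = method)
}

# Residuals after polynomial detrending of order 0 (mean) or 1 (linear),
# applied row-wise to an ROIs/voxels x volumes matrix.
detrendRows <- function(X, order = 1L) {
  n <- ncol(X)
  t0 <- seq_len(n)
  basis <- if (order == 0L) cbind(rep(1, n)) else cbind(1, t0)
  Q <- qr.Q(qr(basis))
  X - (X %*% Q) %*% t(Q)
}
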