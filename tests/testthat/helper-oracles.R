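# Independent brute-force oracles, deliberately written with plain loops and
# textbook formulas, against which the vectorized implementations are checked.

oracleTsnr <- function(X, order = 1) {
  apply(X, 1, function(x) {
    t0 <- seq_along(x)
    res <- if (order == 0) x - mean(x) else residuals(lm(x ~ t0))
    mean(x) / sqrt(sum(res^2) / (length(x) - 1))
  })
}

oracleErode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else FALSE,
      if (i < d[1]) mask[i + 1, j, k] else FALSE,
      if (j > 1) mask[i, j - 1, k] else FALSE,
      if (j < d[2]) mask[i, j + 1, k] else FALSE,
      if (k > 1) mask[i, j, k - 1] else FALSE,
      if (k < d[3]) mask[i, j, k + 1] else FALSE)
    out[i, j, k] <- all(nb)
  }
  out
}

# trilinear interpolation of one point in 0-based voxel coordinates
oracleTrilinear <- function(values, v) {
  d <- dim(values)
  f <- floor(v); w <- v - f
  for (a in 1:3) if (f[a] == d[a] - 1 && w[a] == 0) { f[a] <- f[a] - 1; w[a] <- 1 }
  if (any(f < 0) || any(f > d - 2)) return(NA_real_)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    val <- values[f[1] + dx + 1, f[2] + dy + 1, f[3] + dz + 1]
    acc <- acc + wt * val
  }
  acc
}

oracleSoftMean <- function(arrs) {
  d <- dim(arrs[[1]])
  out <- array(NA_real_, dim = d)
  cov <- array(0, dim = d)
  for (i in seq_along(out)) {
    vals <- vapply(arrs, function(a) a[i], 0)
    ok <- is.finite(vals)
    cov[i] <- mean(ok)
    if (any(ok)) out[i] <- sum(vals[ok]) / sum(ok)
  }
  list(values = out, coverage = cov)
}

oraclePearson <- function(X) {
  R <- nrow(X)
  M <- diag(1, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i == j) next
    xi <- X[i, ] - mean(X[i, ]); xj <- X[j, ] - mean(X[j, ])
    M[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  M
}

oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

oracleFwd <- function(poses, radius = 50) {
  n <- nrow(poses)
  fwd <- numeric(n)
  for (t in 2:n) {
    fwd[t] <- sum(abs(poses[t, 4:6] - poses[t - 1, 4:6])) +
      radius * sum(abs(poses[t, 1:3] - poses[t - 1, 1:3]))
  }
  fwd
}

oracleCentroid <- function(mask, affine) {
  d <- dim(mask)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k]) {
      h <- affine %*% c(i - 1, j - 1, k - 1, 1)
      pts <- rbind(pts, h[1:3])
    }
  colMeans(pts)
}

oracleFisherCi <- function(x, y) {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r)
  se <- 1 / sqrt(length(x) - 3)
  tanh(z + c(-1, 1) * qnorm(0.975) * se)
}

# small random 3-D blob mask
randomBlob <- function(d, p = 0.5) array(runif(prod(d)) < p, dim = d)
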