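#' Framewise displacement from per-volume poses
#'
#' The per-volume sum of absolute successive differences of the three
#' translations plus `rotationRadiusMm` times the sum of absolute rotation
#' differences (small-angle arc length on a sphere of that radius). The
#' first volume has FWD 0; the session mean excludes it.
#'
#' @param poses volumes x 6 pose matrix (rx, ry, rz radians; tx, ty, tz mm)
#'   or a [SessionRecord-class].
#' @param rotationRadiusMm sphere radius converting radians to mm; 50 mm is
#'   the adult convention, 35 mm an infant-sized preset.
#' @return list with `perVolume` (numeric, first element 0) and `mean`
#' @export
framewiseDisplacement <- function(poses, rotationRadiusMm = 50) {
  if (is(poses, "SessionRecord")) poses <- poses@poses
  stopifnot(ncol(poses) == 6, nrow(poses) >= 2)
  d <- abs(diff(poses))
  fwd <- c(0, rowSums(d[, 4:6, drop = FALSE]) +
                rotationRadiusMm * rowSums(d[, 1:3, drop = FALSE]))
  list(perVolume = fwd, mean = mean(fwd[-1]))
}

# Participants x edges matrix from a list of Connectome objects (or a ready
# matrix); canonical row-major upper-triangle edge order.
edgeMatrix <- function(connectomes) {
  if (is.matrix(connectomes)) return(connectomes)
  do.call(rbind, lapply(connectomes, function(cn) {
    if (is(cn, "Connectome")) edgeVector(cn) else upperTriRowMajor(cn)
  }))
}

# Participants x edges matrix of SNR products s_i * s_j in edge order.
snrProductMatrix <- function(snrProfiles) {
  P <- if (is.matrix(snrProfiles)) snrProfiles else do.call(rbind, snrProfiles)
  res <- apply(P, 1, function(s) upperTriRowMajor(outer(s, s)))
  if (is.null(dim(res))) matrix(res, ncol = 1) else t(res)
}

#' Edge-wise regression of functional connectivity on SNR
#'
#' For each edge (i, j), ordinary least squares of the standardized
#' connectivity c_ij(p) on the standardized SNR product s_i(p) s_j(p) across
#' participants. With both sides z-scored the slope is the Pearson
#' correlation over participants. The summary tests the mean slope against
#' zero with a one-sample t-test over edges and, as the primary inference, a
#' permutation test that shuffles the participant-to-SNR-profile assignment
#' and recomputes the mean slope.
#'
#' @param connectomes per-participant [Connectome-class] list (or a
#'   participants x edges matrix in canonical edge order).
#' @param snrProfiles per-participant SNR profiles (list or matrix), aligned
#'   with `connectomes`.
#' @param nPermutations permutation count B (default 1000).
#' @param seed integer seed for the permutations.
#' @return list of class `edgeRegression`: per-edge `beta`, `intercept`,
#'   `pValue`; `meanBeta`, `tStatistic`, `tPValue`, `permutationP`,
#'   `nEdges`, `nSkipped`, `nParticipants`
#' @export
edgewiseSnrFcRegression <- function(connectomes, snrProfiles,
                                    nPermutations = 1000, seed = 1L) {
  C <- edgeMatrix(connectomes)
  S <- snrProductMatrix(snrProfiles)
  P <- nrow(C)
  stopifnot(P >= 3, nrow(S) == P, ncol(S) == ncol(C))
  sdS <- apply(S, 2, sd)
  sdC <- apply(C, 2, sd)
  ok <- sdS > 0 & sdC > 0 & colSums(is.na(C)) == 0
  ZC <- zscoreCols(C[, ok, drop = FALSE])
  ZS <- zscoreCols(S[, ok, drop = FALSE])
  if (!any(ok))
    return(structure(list(beta = numeric(0), intercept = numeric(0),
                          pValue = numeric(0), meanBeta = NA_real_,
                          tStatistic = NA_real_, tPValue = NA_real_,
                          permutationP = NA_real_,
                          permutationNull = numeric(0), nEdges = 0L,
                          nSkipped = sum(!ok), nParticipants = P),
                     class = "edgeRegression"))
  beta <- colSums(ZC * ZS) / (P - 1)
  tEdge <- beta * sqrt((P - 2) / pmax(1 - beta^2, .Machine$double.eps))
  pEdge <- 2 * pt(-abs(tEdge), df = P - 2)
  tt <- if (length(beta) > 1) t.test(beta) else
    list(statistic = NA_real_, p.value = NA_real_)
  # permutation null for the mean slope: G[p, q] = <zc_p, zs_q> over edges
  G <- ZC %*% t(ZS) / ((P - 1) * ncol(ZC))
  obs <- sum(diag(G))
  set.seed(seed)
  perm <- replicate(nPermutations, {
    pr <- sample.int(P)
    sum(G[cbind(seq_len(P), pr)])
  })
  pPerm <- (1 + sum(abs(perm) >= abs(obs))) / (nPermutations + 1)
  structure(list(beta = beta, intercept = rep(0, length(beta)),
                 pValue = pEdge, meanBeta = mean(beta),
                 tStatistic = unname(tt$statistic), tPValue = tt$p.value,
                 permutationP = pPerm, permutationNull = perm,
                 nEdges = sum(ok), nSkipped = sum(!ok), nParticipants = P),
            class = "edgeRegression")
}

#' @export
print.edgeRegression <- function(x, ...) {
  cat(sprintf("edge-wise SNR-Fc regression: %d participants, %d edges (%d skipped)\n",
              x$nParticipants, x$nEdges, x$nSkipped))
  cat(sprintf("  mean beta %.4f, t = %.2f (p = %.3g), permutation p = %.4g\n",
              x$meanBeta, x$tStatistic, x$tPValue, x$permutationP))
  invisible(x)
}

#' Predictor comparison: SNR versus connectivity across segments
#'
#' For each edge, ordinary least squares of the standardized segment-2
#' connectivity on two standardized regressors from segment 1: the SNR
#' product s_i s_j and the connectivity c_ij. The standardized coefficients
#' are comparable between predictors; their means over edges carry
#' normal-approximation 95% intervals (descriptive -- edges are dependent).
#'
#' @param seg1Connectomes,seg2Connectomes per-participant connectomes for
#'   the two segments (lists or participants x edges matrices).
#' @param seg1SnrProfiles per-participant SNR profiles for segment 1.
#' @param collinearityLimit skip edges whose two regressors correlate beyond
#'   this magnitude (default 0.999).
#' @return list of class `predictorComparison`: per-edge `betaSnr`,
#'   `betaFc`; `meanBetaSnr`, `meanBetaFc` with `ciSnr`, `ciFc`; `nEdges`,
#'   `nSkipped`
#' @export
predictorComparison <- function(seg1Connectomes, seg2Connectomes,
                                seg1SnrProfiles,
                                collinearityLimit = 0.999) {
  C1 <- edgeMatrix(seg1Connectomes)
  C2 <- edgeMatrix(seg2Connectomes)
  S <- snrProductMatrix(seg1SnrProfiles)
  P <- nrow(C1)
  stopifnot(P >= 3, nrow(C2) == P, nrow(S) == P)
  ok <- apply(S, 2, sd) > 0 & apply(C1, 2, sd) > 0 & apply(C2, 2, sd) > 0 &
    colSums(is.na(C1) | is.na(C2)) == 0
  ZS <- zscoreCols(S[, ok, drop = FALSE])
  Z1 <- zscoreCols(C1[, ok, drop = FALSE])
  Z2 <- zscoreCols(C2[, ok, drop = FALSE])
  a <- colSums(ZS * Z1) / (P - 1)      # regressor intercorrelation
  usable <- abs(a) <= collinearityLimit
  b1 <- colSums(ZS * Z2) / (P - 1)     # cor(SNR product, target)
  b2 <- colSums(Z1 * Z2) / (P - 1)     # cor(seg1 Fc, target)
  den <- 1 - a^2
  betaSnr <- ((b1 - a * b2) / den)[usable]
  betaFc <- ((b2 - a * b1) / den)[usable]
  ci <- function(x) mean(x) + c(-1, 1) * 1.96 * sd(x) / sqrt(length(x))
  structure(list(betaSnr = betaSnr, betaFc = betaFc,
                 meanBetaSnr = mean(betaSnr), meanBetaFc = mean(betaFc),
                 ciSnr = ci(betaSnr), ciFc = ci(betaFc),
                 nEdges = sum(usable),
                 nSkipped = sum(!ok) + sum(!usable)),
            class = "predictorComparison")
}

#' @export
print.predictorComparison <- function(x, ...) {
  cat(sprintf("predictor comparison over %d edges (%d skipped)\n",
              x$nEdges, x$nSkipped))
  cat(sprintf("  mean beta_SNR %.3f [%.3f, %.3f]; mean beta_FC %.3f [%.3f, %.3f]\n",
              x$meanBetaSnr, x$ciSnr[1], x$ciSnr[2],
              x$meanBetaFc, x$ciFc[1], x$ciFc[2]))
  invisible(x)
}

#' Connectome-stability regression on explanatory variables
#'
#' Ordinary least squares of per-participant (full-session model, five
#' explanatory variables: mean SNR, mean FWD, inter-session interval, age at
#' first session, head circumference) or per-session (split-session model,
#' two variables: mean SNR, mean FWD) connectome stability. Explanatory
#' variables are z-scored before fitting, so the returned coefficients are
#' standardized.
#'
#' @param stabilities numeric vector of within-participant Spearman
#'   stability values.
#' @param covariateTable data.frame of explanatory variables, one column per
#'   variable in the declared order.
#' @param model "full_session" (expects 5 variables) or "split_session"
#'   (expects 2); "any" accepts any column count.
#' @return list of class `stabilityModel`: `coefficients` (standardized,
#'   named), `pValues`, `n`, `model`
#' @export
stabilityRegression <- function(stabilities, covariateTable,
                                model = c("full_session", "split_session",
                                          "any")) {
  model <- match.arg(model)
  X <- as.data.frame(covariateTable)
  want <- c(full_session = 5L, split_session = 2L, any = ncol(X))[model]
  if (ncol(X) != want)
    stop(sprintf("model '%s' expects %d explanatory variables, got %d",
                 model, want, ncol(X)))
  stopifnot(length(stabilities) == nrow(X))
  flat <- vapply(X, sd, 0) == 0
  if (any(flat))
    stop("zero-variance explanatory variable(s): ",
         paste(names(X)[flat], collapse = ", "))
  Z <- as.data.frame(lapply(X, zscore))
  qrX <- qr(as.matrix(cbind(1, Z)))
  if (qrX$rank < ncol(Z) + 1) {
    drop <- setdiff(seq_len(ncol(Z) + 1), qrX$pivot[seq_len(qrX$rank)]) - 1
    stop("rank-deficient design; collinear columns: ",
         paste(names(Z)[drop], collapse = ", "))
  }
  fit <- lm(stabilities ~ ., data = Z)
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(coefficients = coef(fit)[-1],
                 pValues = sm[-1, "Pr(>|t|)"],
                 n = length(stabilities), model = model, fit = fit),
            class = "stabilityModel")
}

#' @export
print.stabilityModel <- function(x, ...) {
  cat(sprintf("stability regression (%s, n = %d)\n", x$model, x$n))
  for (v in names(x$coefficients))
    cat(sprintf("  %-10s beta = %+.3f (p = %.3g)\n", v, x$coefficients[[v]],
                x$pValues[[v]]))
  invisible(x)
}

#' Pearson correlation of stability with one covariate
#'
#' @param stabilities numeric vector.
#' @param covariate numeric vector of the same length (n >= 4).
#' @return list with `r`, `ci` (Fisher-z 95% interval), `p`, `n`
#' @export
covariateCorrelation <- function(stabilities, covariate) {
  stopifnot(length(stabilities) == length(covariate),
            length(stabilities) >= 4)
  if (sd(stabilities) == 0 || sd(covariate) == 0)
    stop("zero variance in input")
  ct <- cor.test(stabilities, covariate)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(stabilities))
}
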