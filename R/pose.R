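#' Construct a rigid-body head pose
#'
#' @param rotations numeric(3) rotations in radians about x, y, z (applied in
#'   that order).
#' @param translations numeric(3) translations in mm (x = left-right,
#'   y = posterior-anterior, z = inferior-superior; RAS+).
#' @param center numeric(3) native-mm point the rotations pivot about
#'   (default the origin).
#' @return a [HeadPose-class]
#' @examples
#' p <- headPose(rotations = c(0, 0, pi / 36), translations = c(1, 2, 0))
#' poseAffine(p)
#' @export
headPose <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                     center = c(0, 0, 0)) {
  new("HeadPose", rotations = as.numeric(rotations),
      translations = as.numeric(translations), center = as.numeric(center))
}

rotationMatrixXYZ <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' @rdname poseAffine
#' @export
setMethod("poseAffine", "HeadPose", function(x) {
  R <- rotationMatrixXYZ(x@rotations)
  A <- diag(4)
  A[1:3, 1:3] <- R
  # x' = R (x - c) + c + t
  A[1:3, 4] <- x@center - R %*% x@center + x@translations
  A
})

#' Recover the 6 rigid-body parameters from a rigid affine
#'
#' Inverse of [poseAffine()] for rotations within (-pi/2, pi/2) about y.
#' The round trip parameters -> affine -> parameters is the identity to
#' better than 1e-8.
#'
#' @param affine 4x4 rigid affine (orthonormal 3x3 block, determinant +1).
#' @param center numeric(3) rotation center assumed when building the pose.
#' @return a [HeadPose-class]
#' @export
affineToPose <- function(affine, center = c(0, 0, 0)) {
  R <- affine[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("affine is not a proper rigid transform")
  ry <- asin(max(-1, min(1, -R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  rot <- c(rx, ry, rz)
  trans <- affine[1:3, 4] - center + R %*% center
  headPose(rotations = rot, translations = as.numeric(trans), center = center)
}

#' Apply a head pose to native-space points
#'
#' @param pose a [HeadPose-class]
#' @param pts n x 3 matrix (or length-3 vector) of native mm coordinates.
#' @return n x 3 matrix of scanner mm coordinates
#' @export
applyPose <- function(pose, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  A <- poseAffine(pose)
  h <- cbind(pts, 1) %*% t(A)
  h[, 1:3, drop = FALSE]
}

# Default between-session repositioning ranges (mm / radians).
# Posterior-anterior and left-right spans follow the observed brainmask
# centroid spread in the cohort this emulates; the superior-inferior span and
# the rotation limits are configurable defaults (not reported quantities).
defaultPoseRanges <- function() {
  list(lr = c(-14, 7), pa = c(-5, 29), si = c(-5, 5),
       rot = c(-5, 5) * pi / 180)
}

# Build a between-session pose from 6 uniform quantiles in [0, 1]
# (tx, ty, tz, rx, ry, rz). Used by sampleHeadPose and by the cohort
# generator, which mixes subject-level and session-level quantiles to give
# each subject a partially consistent resting position.
poseFromQuantiles <- function(u, ranges = defaultPoseRanges()) {
  stopifnot(length(u) == 6L, all(u >= 0 & u <= 1))
  tr <- c(ranges$lr[1] + diff(ranges$lr) * u[1],
          ranges$pa[1] + diff(ranges$pa) * u[2],
          ranges$si[1] + diff(ranges$si) * u[3])
  ro <- ranges$rot[1] + diff(ranges$rot) * u[4:6]
  headPose(rotations = ro, translations = tr)
}

#' Draw a head pose
#'
#' `between_session` draws translations uniformly from the between-session
#' repositioning ranges (posterior-anterior -5..+29 mm, left-right
#' -14..+7 mm, superior-inferior +/-5 mm by default) and rotations uniformly
#' within +/-5 degrees. `within_session_jitter` draws a small perturbation
#' around `reference` (SD 1 mm / 0.5 degrees at `jitterScale = 1`).
#'
#' @param sessionKind "between_session" or "within_session_jitter".
#' @param jitterScale multiplier on the within-session jitter SDs;
#'   0 returns the reference pose exactly.
#' @param reference a [HeadPose-class] the jitter is centered on
#'   (required for `within_session_jitter`).
#' @param seed optional integer; when given, the draw is a pure function of it.
#' @param ranges list of between-session ranges as in `defaultPoseRanges`.
#' @return a [HeadPose-class]
#' @export
sampleHeadPose <- function(sessionKind = c("between_session",
                                           "within_session_jitter"),
                           jitterScale = 1, reference = NULL, seed = NULL,
                           ranges = defaultPoseRanges()) {
  sessionKind <- match.arg(sessionKind)
  if (!is.null(seed)) set.seed(seed)
  if (sessionKind == "between_session")
    return(poseFromQuantiles(runif(6), ranges))
  if (is.null(reference)) reference <- headPose()
  headPose(rotations = reference@rotations +
             rnorm(3, 0, 0.5 * pi / 180 * jitterScale),
           translations = reference@translations + rnorm(3, 0, 1 * jitterScale),
           center = reference@center)
}

# volumes x 6 pose matrix row -> HeadPose (FSL .par order: rx ry rz tx ty tz)
poseFromRow <- function(row, center = c(0, 0, 0)) {
  headPose(rotations = row[1:3], translations = row[4:6], center = center)
}

poseToRow <- function(pose) c(pose@rotations, pose@translations)
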