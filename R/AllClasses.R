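#' CoilField: a scalar sensitivity/SNR field on a regular 3-D grid
#'
#' Holds nonnegative scalar values (coil sensitivity, or a group-average tSNR
#' estimate, "SNR-coil") on a regular 3-D grid in scanner coordinates, with a
#' voxel-to-mm affine (0-based voxel indices, RAS+ mm). `coverage` records,
#' per voxel, the fraction (or count) of contributing sources; values are
#' undefined (NA) exactly where coverage is 0.
#'
#' @slot values 3-D numeric array; NA where undefined.
#' @slot affine 4x4 voxel-to-scanner-mm affine (invertible).
#' @slot coverage 3-D numeric array, same dim as `values`; 0 where undefined.
#' @aliases CoilField
#' @exportClass CoilField
setClass("CoilField",
  representation(values = "array", affine = "matrix", coverage = "array"))

setValidity("CoilField", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (!identical(dim(object@values), dim(object@coverage)))
    msg <- c(msg, "coverage must have the same dimensions as values")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  else {
    sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
    if (any(sp <= 0)) msg <- c(msg, "grid spacing must be strictly positive")
  }
  def <- object@coverage > 0
  v <- object@values
  if (any(is.na(v[def])) || any(!is.na(v[!def])))
    msg <- c(msg, "values must be NA exactly where coverage is 0")
  if (any(v[def] < 0) || any(!is.finite(v[def])))
    msg <- c(msg, "defined values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' HeadPose: a 6-parameter rigid-body head pose
#'
#' Three rotations (radians, applied about x then y then z) and three
#' translations (mm), mapping native head coordinates into scanner mm
#' (RAS+). The equivalent 4x4 rigid affine is obtained with [poseAffine()].
#' Rotations are applied about `center` (native mm; the volume center by
#' convention, the origin for synthetic sessions).
#'
#' @slot rotations numeric(3), radians (rx, ry, rz).
#' @slot translations numeric(3), mm (tx, ty, tz).
#' @slot center numeric(3), native-mm rotation center.
#' @aliases HeadPose
#' @exportClass HeadPose
setClass("HeadPose",
  representation(rotations = "numeric", translations = "numeric",
                 center = "numeric"),
  prototype(rotations = c(0, 0, 0), translations = c(0, 0, 0),
            center = c(0, 0, 0)))

setValidity("HeadPose", function(object) {
  if (length(object@rotations) != 3L || length(object@translations) != 3L ||
      length(object@center) != 3L)
    return("rotations, translations and center must each have length 3")
  if (!all(is.finite(c(object@rotations, object@translations, object@center))))
    return("pose parameters must be finite")
  TRUE
})

#' SubjectSpec: latent per-participant ground truth for simulation
#'
#' The participant's trait connectome (the "trait-like, intrinsic" component
#' of functional connectivity), head radius, and session covariates.
#'
#' @slot traitConnectome symmetric positive-semidefinite correlation matrix,
#'   unit diagonal.
#' @slot headRadius head radius in mm (cortical ROI shell scale).
#' @slot covariates named list: ages at each session (weeks PMA), head
#'   circumference (cm), inter-session interval (weeks).
#' @aliases SubjectSpec
#' @exportClass SubjectSpec
setClass("SubjectSpec",
  representation(traitConnectome = "matrix", headRadius = "numeric",
                 covariates = "list"))

setValidity("SubjectSpec", function(object) {
  msg <- character()
  C <- object@traitConnectome
  if (nrow(C) != ncol(C)) msg <- c(msg, "traitConnectome must be square")
  else {
    if (max(abs(diag(C) - 1)) > 1e-8)
      msg <- c(msg, "traitConnectome must have unit diagonal")
    if (max(abs(C - t(C))) > 1e-8)
      msg <- c(msg, "traitConnectome must be symmetric")
    if (any(C < -1 - 1e-12 | C > 1 + 1e-12))
      msg <- c(msg, "traitConnectome entries must be in [-1, 1]")
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10)
      msg <- c(msg, sprintf("traitConnectome must be PSD (min eigenvalue %.3g)", ev))
  }
  if (object@headRadius <= 0) msg <- c(msg, "headRadius must be positive")
  if (length(msg)) msg else TRUE
})

#' SessionRecord: one scanning session
#'
#' An ROI-by-volume BOLD matrix together with its repetition time, per-volume
#' rigid-body head poses (volumes x 6: rx, ry, rz in radians then tx, ty, tz
#' in mm, the FSL `.par` column order), native-space ROI center coordinates
#' and per-session covariates.
#'
#' @slot roiTimeseries ROIs x volumes numeric matrix (BOLD-like units).
#' @slot tr repetition time in seconds.
#' @slot poses volumes x 6 numeric matrix of rigid-body parameters.
#' @slot roiCenters ROIs x 3 matrix, native mm.
#' @slot covariates named list (age, head circumference, session index, ...).
#' @slot participantId character scalar.
#' @slot sessionIndex integer scalar (1-based).
#' @aliases SessionRecord
#' @exportClass SessionRecord
setClass("SessionRecord",
  representation(roiTimeseries = "matrix", tr = "numeric", poses = "matrix",
                 roiCenters = "matrix", covariates = "list",
                 participantId = "character", sessionIndex = "integer"))

setValidity("SessionRecord", function(object) {
  msg <- character()
  if (nrow(object@poses) != ncol(object@roiTimeseries))
    msg <- c(msg, "number of pose rows must equal number of volumes")
  if (ncol(object@poses) != 6L)
    msg <- c(msg, "poses must have 6 columns")
  if (any(!is.finite(object@roiTimeseries)))
    msg <- c(msg, "roiTimeseries must contain no non-finite samples")
  if (nrow(object@roiCenters) != nrow(object@roiTimeseries) ||
      ncol(object@roiCenters) != 3L)
    msg <- c(msg, "roiCenters must be ROIs x 3")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Segment: a contiguous stretch of a session's timeseries
#'
#' Either the full session or one of the two split-session halves separated
#' by a discarded middle gap. Volume ranges are 0-based and half-open.
#'
#' @slot data ROIs x volumes numeric matrix.
#' @slot tr repetition time in seconds.
#' @slot parentId parent session identifier.
#' @slot segmentIndex "full", "split-1" or "split-2".
#' @slot range integer(2), 0-based half-open volume range in the parent.
#' @aliases Segment
#' @exportClass Segment
setClass("Segment",
  representation(data = "matrix", tr = "numeric", parentId = "character",
                 segmentIndex = "character", range = "integer"))

setValidity("Segment", function(object) {
  msg <- character()
  if (!object@segmentIndex %in% c("full", "split-1", "split-2"))
    msg <- c(msg, "segmentIndex must be one of 'full', 'split-1', 'split-2'")
  if (length(object@range) != 2L || object@range[2] < object@range[1])
    msg <- c(msg, "range must be an increasing 0-based half-open pair")
  if (diff(object@range) != ncol(object@data))
    msg <- c(msg, "range width must equal the number of volumes in data")
  if (length(msg)) msg else TRUE
})

#' Connectome: a symmetric ROI-by-ROI Pearson correlation matrix
#'
#' Unit diagonal; edges corresponding to constant (zero-variance) ROI series
#' are NA. The canonical edge vectorization used project-wide is the upper
#' triangle in row-major order over i < j (see [edgeVector()]).
#'
#' @slot mat ROI x ROI symmetric Pearson matrix.
#' @slot roiIds integer vector of retained ROI indices (1-based labels into
#'   the original parcellation).
#' @aliases Connectome
#' @exportClass Connectome
setClass("Connectome",
  representation(mat = "matrix", roiIds = "integer"))

setValidity("Connectome", function(object) {
  msg <- character()
  M <- object@mat
  if (nrow(M) != ncol(M)) msg <- c(msg, "mat must be square")
  else {
    if (length(object@roiIds) != nrow(M))
      msg <- c(msg, "roiIds length must equal matrix dimension")
    d <- M[!is.na(M)]
    if (any(d < -1 - 1e-9 | d > 1 + 1e-9))
      msg <- c(msg, "entries must be in [-1, 1]")
    if (max(abs(M - t(M)), na.rm = TRUE) > 1e-12)
      msg <- c(msg, "mat must be symmetric to 1e-12")
  }
  if (length(msg)) msg else TRUE
})

#' RSM: participants-by-participants representational similarity matrix
#'
#' Entry (p, q) is the Spearman rank correlation between participant p's
#' segment-1 vector (connectome edges or SNR profile) and participant q's
#' segment-2 vector. Rows and columns index different segments, so the
#' matrix is not assumed symmetric; the diagonal holds within-participant
#' stability.
#'
#' @slot mat P x P numeric matrix, entries in [-1, 1].
#' @slot ids character vector of participant identifiers.
#' @aliases RSM
#' @exportClass RSM
setClass("RSM", representation(mat = "matrix", ids = "character"))

setValidity("RSM", function(object) {
  msg <- character()
  if (nrow(object@mat) != ncol(object@mat)) msg <- c(msg, "mat must be square")
  if (length(object@ids) != nrow(object@mat))
    msg <- c(msg, "ids length must match matrix dimension")
  d <- object@mat[!is.na(object@mat)]
  if (any(d < -1 - 1e-9 | d > 1 + 1e-9))
    msg <- c(msg, "entries must be in [-1, 1]")
  if (length(msg)) msg else TRUE
})
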