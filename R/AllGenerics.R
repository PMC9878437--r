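#' Field values of a CoilField
#' @param x a [CoilField-class]
#' @return 3-D array of field values (NA where undefined)
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "CoilField", function(x) x@values)

#' Coverage of a CoilField
#' @param x a [CoilField-class]
#' @return 3-D array: per-voxel fraction (or count) of contributing sources
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname coverage
#' @export
setMethod("coverage", "CoilField", function(x) x@coverage)

#' Voxel-to-scanner affine of a gridded object
#' @param x a [CoilField-class]
#' @return 4x4 voxel-to-mm affine (0-based voxel indices)
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))

#' @rdname gridAffine
#' @export
setMethod("gridAffine", "CoilField", function(x) x@affine)

#' Rigid-body affine of a head pose
#'
#' Builds the 4x4 rigid transform mapping native mm to scanner mm:
#' rotations are applied about the x, then y, then z axes (about the pose
#' center), followed by the translations.
#'
#' @param x a [HeadPose-class]
#' @return 4x4 rigid affine with orthonormal 3x3 block, determinant +1
#' @export
setGeneric("poseAffine", function(x) standardGeneric("poseAffine"))

#' Pose parameter accessors
#' @param x a [HeadPose-class]
#' @return numeric(3): rotations in radians, or translations in mm
#' @export
setGeneric("rotations", function(x) standardGeneric("rotations"))

#' @rdname rotations
#' @export
setMethod("rotations", "HeadPose", function(x) x@rotations)

#' @rdname rotations
#' @export
setGeneric("translations", function(x) standardGeneric("translations"))

#' @rdname rotations
#' @export
setMethod("translations", "HeadPose", function(x) x@translations)

#' Canonical edge vector of a connectome
#'
#' Upper-triangle entries in row-major order over i < j; the project-wide
#' edge vectorization shared by all cross-module edge indexing.
#'
#' @param x a [Connectome-class] or a square matrix
#' @return numeric vector of length R(R-1)/2
#' @export
setGeneric("edgeVector", function(x) standardGeneric("edgeVector"))

#' @rdname edgeVector
#' @export
setMethod("edgeVector", "Connectome", function(x) upperTriRowMajor(x@mat))

#' @rdname edgeVector
#' @export
setMethod("edgeVector", "matrix", function(x) upperTriRowMajor(x))

#' Matrix view of similarity and connectome objects
#' @param x an [RSM-class] or [Connectome-class]
#' @return the underlying numeric matrix
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))

#' @rdname similarityMatrix
#' @export
setMethod("similarityMatrix", "RSM", function(x) {
  m <- x@mat
  dimnames(m) <- list(x@ids, x@ids)
  m
})

#' Connectivity matrix of a Connectome
#' @param x a [Connectome-class]
#' @return ROI x ROI symmetric Pearson matrix
#' @export
setGeneric("connectivityMatrix", function(x) standardGeneric("connectivityMatrix"))

#' @rdname connectivityMatrix
#' @export
setMethod("connectivityMatrix", "Connectome", function(x) x@mat)

#' ROI timeseries of a session or segment
#' @param x a [SessionRecord-class] or [Segment-class]
#' @return ROIs x volumes numeric matrix
#' @export
setGeneric("roiTimeseries", function(x) standardGeneric("roiTimeseries"))

#' @rdname roiTimeseries
#' @export
setMethod("roiTimeseries", "SessionRecord", function(x) x@roiTimeseries)

#' @rdname roiTimeseries
#' @export
setMethod("roiTimeseries", "Segment", function(x) x@data)

#' Per-volume pose matrix of a session
#' @param x a [SessionRecord-class]
#' @return volumes x 6 matrix (rx, ry, rz radians; tx, ty, tz mm)
#' @export
setGeneric("poseMatrix", function(x) standardGeneric("poseMatrix"))

#' @rdname poseMatrix
#' @export
setMethod("poseMatrix", "SessionRecord", function(x) x@poses)

setMethod("show", "CoilField", function(object) {
  d <- dim(object@values)
  sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  def <- mean(object@coverage > 0)
  cat(sprintf("CoilField: %d x %d x %d grid, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  defined voxels: %.1f%%; value range [%.3g, %.3g]\n",
              100 * def, min(object@values, na.rm = TRUE),
              max(object@values, na.rm = TRUE)))
})

setMethod("show", "HeadPose", function(object) {
  cat(sprintf("HeadPose: rot (deg) [%.2f, %.2f, %.2f], trans (mm) [%.2f, %.2f, %.2f]\n",
              object@rotations[1] * 180 / pi, object@rotations[2] * 180 / pi,
              object@rotations[3] * 180 / pi, object@translations[1],
              object@translations[2], object@translations[3]))
})

setMethod("show", "SessionRecord", function(object) {
  cat(sprintf("SessionRecord '%s' (session %d): %d ROIs x %d volumes, TR %.3f s\n",
              object@participantId, object@sessionIndex,
              nrow(object@roiTimeseries), ncol(object@roiTimeseries), object@tr))
})

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment %s of '%s': %d ROIs x %d volumes [%d, %d)\n",
              object@segmentIndex, object@parentId, nrow(object@data),
              ncol(object@data), object@range[1], object@range[2]))
})

setMethod("show", "Connectome", function(object) {
  nEdge <- sum(!is.na(upperTriRowMajor(object@mat)))
  cat(sprintf("Connectome: %d ROIs, %d/%d defined edges\n", nrow(object@mat),
              nEdge, length(upperTriRowMajor(object@mat))))
})

setMethod("show", "RSM", function(object) {
  cat(sprintf("RSM: %d participants; mean within %.3f, mean between %.3f\n",
              nrow(object@mat), mean(diag(object@mat), na.rm = TRUE),
              mean(object@mat[row(object@mat) != col(object@mat)], na.rm = TRUE)))
})
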