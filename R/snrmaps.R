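#' ScalarMap: a voxelwise scalar map with an affine and space tag
#'
#' Used for voxelwise tSNR maps in native or scanner space. Values are NA
#' outside the mask; infinite values are legal (they flag zero residual SD)
#' but are excluded from soft means.
#'
#' @slot values 3-D numeric array (NA = undefined).
#' @slot affine 4x4 voxel-to-mm affine (0-based voxel indices).
#' @slot space "native" or "scanner".
#' @aliases ScalarMap
#' @exportClass ScalarMap
setClass("ScalarMap",
  representation(values = "array", affine = "matrix", space = "character"))

setValidity("ScalarMap", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be 3-D")
  if (!identical(dim(object@affine), c(4L, 4L)) ||
      abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be an invertible 4x4 matrix")
  if (!object@space %in% c("native", "scanner"))
    msg <- c(msg, "space must be 'native' or 'scanner'")
  if (length(msg)) msg else TRUE
})

#' Construct a ScalarMap
#' @param values 3-D numeric array (NA where undefined).
#' @param affine 4x4 voxel-to-mm affine; default centered 1 mm grid.
#' @param space "native" or "scanner".
#' @return a [ScalarMap-class]
#' @export
scalarMap <- function(values, affine = NULL, space = "native") {
  if (is.null(affine)) affine <- centeredGridAffine(dim(values), 1)
  new("ScalarMap", values = values, affine = affine, space = space)
}

setMethod("show", "ScalarMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarMap (%s space): %d x %d x %d, %.1f%% defined\n",
              object@space, d[1], d[2], d[3],
              100 * mean(!is.na(object@values))))
})

#' Temporal signal-to-noise ratio of timeseries
#'
#' tSNR per series: the temporal mean divided by the standard deviation of
#' the residuals after polynomial detrending (order 0 removes the mean,
#' order 1 additionally removes a linear trend). The SD uses the unbiased
#' (n - 1) denominator. A zero residual SD yields `Inf` (flagged, not
#' dropped); a warning reports how many series were flagged.
#'
#' @param timeseries voxels-or-ROIs x volumes numeric matrix (a single
#'   series may be given as a vector).
#' @param detrendOrder 0 or 1 (default 1, linear detrend).
#' @return numeric vector of per-series tSNR values
#' @examples
#' computeTsnr(c(98, 100, 102, 100, 100), detrendOrder = 0)  # 100 / sqrt(2)
#' @export
computeTsnr <- function(timeseries, detrendOrder = 1L) {
  if (is.null(dim(timeseries))) timeseries <- matrix(timeseries, nrow = 1)
  stopifnot(ncol(timeseries) >= 3, detrendOrder %in% c(0L, 1L))
  res <- detrendRows(timeseries, order = as.integer(detrendOrder))
  sdRes <- sqrt(rowSums(res^2) / (ncol(timeseries) - 1))
  mu <- rowMeans(timeseries)
  # residuals at numerical-noise level count as zero (e.g. a pure ramp)
  flat <- sdRes <= 1e-10 * pmax(apply(abs(timeseries), 1, max), 1)
  sdRes[flat] <- 0
  out <- mu / sdRes
  nInf <- sum(!is.finite(out))
  if (nInf > 0)
    warning(sprintf("%d series with zero residual SD flagged infinite", nInf))
  out
}

#' Morphological erosion of a binary mask (6-connected)
#'
#' A voxel is kept iff all six face neighbours (and itself) are in the mask;
#' applied `iterations` times. The result is always a subset of the input.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param iterations number of erosion passes.
#' @return 3-D logical array
#' @export
erodeMask <- function(mask, iterations = 1L) {
  m <- array(as.logical(mask), dim = dim(mask))
  d <- dim(m)
  stopifnot(length(d) == 3L)
  for (it in seq_len(iterations)) {
    out <- m
    # face neighbours outside the volume count as background
    sh <- function(ax, by) {
      r <- array(FALSE, dim = d)
      idx <- lapply(d, seq_len)
      src <- idx
      if (by == 1) { idx[[ax]] <- seq_len(d[ax] - 1); src[[ax]] <- 2:d[ax] }
      else { idx[[ax]] <- 2:d[ax]; src[[ax]] <- seq_len(d[ax] - 1) }
      r[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
      r
    }
    for (ax in 1:3) for (by in c(1, -1)) out <- out & sh(ax, by)
    m <- out
  }
  if (!any(m)) warning("erosion produced an empty mask")
  m
}

# Normalise target grid specifications for reslicing.
asGridSpec <- function(spec) {
  if (is.list(spec) && !is.null(spec$dims)) {
    dims <- as.integer(spec$dims)
    affine <- if (!is.null(spec$affine)) spec$affine else
      centeredGridAffine(dims, if (is.null(spec$spacing)) 1 else spec$spacing)
    return(list(dims = dims, affine = affine))
  }
  stop("target grid spec must be a list with dims and spacing or affine")
}

#' Reslice a native-space map into scanner space
#'
#' Pull-style resampling: every target voxel center is mapped back through
#' the rigid pose (scanner -> native mm) and the map's affine (native mm ->
#' voxel) and interpolated. Voxels that map outside the source's defined
#' region become NA (missing), never zero.
#'
#' @param map a [ScalarMap-class] in native space.
#' @param poseOrAffine a [HeadPose-class] or 4x4 rigid affine mapping native
#'   mm to scanner mm.
#' @param targetGrid list with `dims` and `spacing` (default 1 mm isotropic)
#'   or `affine`.
#' @param method "trilinear" (default) or "nearest".
#' @return a [ScalarMap-class] in scanner space
#' @export
resliceToScanner <- function(map, poseOrAffine,
                             targetGrid = list(dims = dim(map@values),
                                               spacing = 1),
                             method = "trilinear") {
  A <- if (is(poseOrAffine, "HeadPose")) poseAffine(poseOrAffine) else
    poseOrAffine
  if (abs(det(A)) < 1e-12) stop("pose affine is singular")
  tg <- asGridSpec(targetGrid)
  idx <- as.matrix(expand.grid(i = 0:(tg$dims[1] - 1),
                               j = 0:(tg$dims[2] - 1),
                               k = 0:(tg$dims[3] - 1)))
  world <- voxelToWorld(tg$affine, idx)       # scanner mm
  native <- cbind(world, 1) %*% t(solve(A))   # back into native mm
  v <- sampleGridWorld(map@values, map@affine, native[, 1:3, drop = FALSE],
                       method = method)
  scalarMap(array(v, dim = tg$dims), affine = tg$affine, space = "scanner")
}

#' Soft mean of scanner-space maps
#'
#' Per voxel, the mean over only those maps whose value is defined (and
#' finite) there; `coverage` records the fraction of maps contributing.
#' Voxels no map covers are NA with coverage 0.
#'
#' @param maps list of [ScalarMap-class] objects on an identical grid.
#' @return a [CoilField-class] holding the group mean and its coverage
#' @export
softMean <- function(maps) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]]@values)
  A <- maps[[1]]@affine
  for (m in maps) {
    if (!identical(dim(m@values), d) || max(abs(m@affine - A)) > 1e-9)
      stop("all maps must share an identical grid")
  }
  sums <- array(0, dim = d)
  count <- array(0, dim = d)
  for (m in maps) {
    ok <- is.finite(m@values)
    sums[ok] <- sums[ok] + m@values[ok]
    count <- count + ok
  }
  vals <- ifelse(count > 0, sums / pmax(count, 1), NA_real_)
  new("CoilField", values = array(vals, dim = d), affine = A,
      coverage = array(count / length(maps), dim = d))
}

#' ROIAtlas: an integer-labelled voxel grid
#'
#' @slot labels 3-D integer array (0 = background).
#' @slot affine 4x4 voxel-to-native-mm affine.
#' @slot labelTable data.frame mapping `label` to `roi` index.
#' @aliases ROIAtlas
#' @exportClass ROIAtlas
setClass("ROIAtlas",
  representation(labels = "array", affine = "matrix",
                 labelTable = "data.frame"))

setValidity("ROIAtlas", function(object) {
  msg <- character()
  if (any(object@labels < 0)) msg <- c(msg, "labels must be nonnegative")
  lab <- sort(unique(as.integer(object@labels[object@labels > 0])))
  if (!all(lab %in% object@labelTable$label))
    msg <- c(msg, "every nonzero label must be present in the label table")
  if (length(msg)) msg else TRUE
})

#' Construct an ROIAtlas
#' @param labels 3-D integer array (0 = background).
#' @param affine 4x4 voxel-to-native-mm affine (default centered 1 mm grid).
#' @param labelTable data.frame with columns `label` and `roi`; default maps
#'   each nonzero label to itself.
#' @return an [ROIAtlas-class]
#' @export
roiAtlas <- function(labels, affine = NULL, labelTable = NULL) {
  if (is.null(affine)) affine <- centeredGridAffine(dim(labels), 1)
  if (is.null(labelTable)) {
    lab <- sort(unique(as.integer(labels[labels > 0])))
    labelTable <- data.frame(label = lab, roi = seq_along(lab))
  }
  new("ROIAtlas", labels = labels, affine = affine, labelTable = labelTable)
}

#' Predict per-ROI SNR from head pose ("SNR-group")
#'
#' Rigidly reorients the atlas into scanner space with the head pose and
#' averages the coil-field (SNR-coil) values over each ROI's voxels. The
#' resulting profile carries no information from the individual's own
#' timeseries: it reflects head position, orientation and shape alone.
#'
#' @param field a [CoilField-class] (the group SNR-coil map).
#' @param atlas an [ROIAtlas-class] in native space.
#' @param pose a [HeadPose-class] mapping native mm to scanner mm.
#' @param maxOutside maximum tolerated fraction of an ROI's voxels falling
#'   outside field coverage (default 0.01).
#' @return named numeric vector of per-ROI SNR values (names = ROI index),
#'   with attribute `provenance = "group"`
#' @export
predictSnrGroup <- function(field, atlas, pose, maxOutside = 0.01) {
  lab <- as.integer(atlas@labels)
  keep <- lab > 0
  idx <- which(keep) - 1L
  d <- dim(atlas@labels)
  vox <- cbind(idx %% d[1],
               (idx %/% d[1]) %% d[2],
               idx %/% (d[1] * d[2]))
  native <- voxelToWorld(atlas@affine, vox)
  scanner <- applyPose(pose, native)
  v <- sampleField(field, scanner)
  roiOf <- atlas@labelTable$roi[match(lab[keep], atlas@labelTable$label)]
  nOut <- tapply(is.na(v), roiOf, mean)
  bad <- names(nOut)[nOut > maxOutside]
  if (length(bad))
    stop("ROIs falling outside field coverage: ", paste(bad, collapse = ", "))
  prof <- tapply(v, roiOf, mean, na.rm = TRUE)
  out <- as.numeric(prof)
  names(out) <- names(prof)
  attr(out, "provenance") <- "group"
  out
}

#' Per-ROI SNR profile from point ROI centers
#'
#' Single-point variant of [predictSnrGroup()]: samples the field at posed
#' ROI center coordinates (trilinear). Used for ROI-mode synthetic sessions
#' where each ROI is represented by its center.
#'
#' @param field a [CoilField-class].
#' @param centers ROIs x 3 native-mm coordinates.
#' @param pose a [HeadPose-class].
#' @return numeric vector of per-ROI SNR values, provenance "group"
#' @export
snrProfileFromCenters <- function(field, centers, pose) {
  v <- sampleField(field, applyPose(pose, centers))
  if (any(is.na(v)))
    stop("ROIs posed outside field coverage: ",
         paste(which(is.na(v)), collapse = ", "))
  attr(v, "provenance") <- "group"
  v
}

#' Reference-volume pose of a segment
#'
#' Returns the pose at the middle volume of a segment -- the volume a
#' realignment run on that segment alone would use as its reference. The
#' convention is the floor of the segment's midpoint index: for a segment of
#' length L starting at 0-based volume a, the index is `a + floor((L-1)/2)`
#' (a 10-volume segment [0..9] gives index 4; a full 2300-volume session
#' gives 1149).
#'
#' @param poses volumes x 6 pose matrix (FSL .par order) for the session.
#' @param segment integer(2) 0-based half-open volume range, or a
#'   [Segment-class].
#' @return a [HeadPose-class], with attribute `volume` (the 0-based index)
#' @export
poseAtReferenceVolume <- function(poses, segment) {
  rng <- if (is(segment, "Segment")) segment@range else as.integer(segment)
  stopifnot(length(rng) == 2L, rng[2] > rng[1])
  idx <- rng[1] + (rng[2] - rng[1] - 1L) %/% 2L
  if (idx < 0 || idx >= nrow(poses))
    stop(sprintf("reference volume %d out of range [0, %d)", idx, nrow(poses)))
  p <- poseFromRow(poses[idx + 1L, ])
  attr(p, "volume") <- idx
  p
}

#' Centroid ("center of gravity") of a brain mask
#'
#' Unweighted mean of mask-voxel centers mapped through the affine to
#' scanner mm.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices).
#' @return numeric(3): centroid in mm
#' @export
brainmaskCentroid <- function(mask, affine) {
  w <- which(array(as.logical(mask), dim = dim(mask)))
  if (!length(w)) stop("mask is empty")
  d <- dim(mask)
  idx0 <- w - 1L
  vox <- cbind(idx0 %% d[1],
               (idx0 %/% d[1]) %% d[2],
               idx0 %/% (d[1] * d[2]))
  colMeans(voxelToWorld(affine, vox))
}
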