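#' Read / write 6-parameter pose files (.par dialect)
#'
#' One row per volume, six whitespace-separated columns: three rotations in
#' radians then three translations in mm (the FSL realignment `.par`
#' convention).
#'
#' @param path file path.
#' @return volumes x 6 numeric matrix
#' @export
readPoseFile <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6) stop("pose file must have 6 columns: ", path)
  dimnames(m) <- list(NULL, c("rx", "ry", "rz", "tx", "ty", "tz"))
  m
}

#' @rdname readPoseFile
#' @param poses volumes x 6 matrix or a [SessionRecord-class].
#' @export
writePoseFile <- function(poses, path) {
  if (is(poses, "SessionRecord")) poses <- poses@poses
  write.table(format(poses, digits = 10, scientific = FALSE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write ROI-by-time timeseries TSV
#'
#' Rows are ROIs, columns volumes; a header row labels volumes.
#'
#' @param path file path.
#' @return ROIs x volumes numeric matrix
#' @export
readTimeseriesTsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t",
                       check.names = FALSE))
}

#' @rdname readTimeseriesTsv
#' @param x ROIs x volumes matrix or a [SessionRecord-class].
#' @export
writeTimeseriesTsv <- function(x, path) {
  if (is(x, "SessionRecord")) x <- x@roiTimeseries
  colnames(x) <- sprintf("V%04d", seq_len(ncol(x)) - 1L)
  write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory layout
#'
#' One ROI-by-time TSV and one `.par` pose file per session, an ROI-center
#' TSV per subject, and a JSON ledger with covariates, seeds and base
#' poses.
#'
#' @param cohort result of [makeCohort()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame (also written as `manifest.csv`)
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$sessions, function(s) {
    stem <- sprintf("%s_ses-%d", s@participantId, s@sessionIndex)
    tsPath <- file.path(dir, paste0(stem, "_bold.tsv"))
    poPath <- file.path(dir, paste0(stem, "_motion.par"))
    cePath <- file.path(dir, paste0(s@participantId, "_centers.tsv"))
    writeTimeseriesTsv(s, tsPath)
    writePoseFile(s, poPath)
    if (!file.exists(cePath))
      write.table(s@roiCenters, cePath, quote = FALSE, sep = "\t",
                  row.names = FALSE, col.names = c("x", "y", "z"))
    data.frame(participant = s@participantId, session = s@sessionIndex,
               tr = s@tr, timeseries = tsPath, poses = poPath,
               centers = cePath, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  led <- cohort$ledger
  jsonlite::write_json(
    list(ids = led$ids, covariates = led$covariates, seed = led$seed,
         basePoses = lapply(led$basePoses, function(ps)
           lapply(ps, poseToRow)),
         trueSnr = led$trueSnr),
    file.path(dir, "ledger.json"), digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a session manifest
#'
#' A CSV with columns `participant`, `session`, `tr`, `timeseries`, `poses`
#' and optionally `centers`. Every referenced path must exist; participants
#' whose session count differs from the declared design trigger a warning.
#'
#' @param path manifest CSV path.
#' @param sessionsPerSubject declared design (default 2).
#' @return manifest data.frame
#' @export
readManifest <- function(path, sessionsPerSubject = 2) {
  m <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("participant", "session", "tr", "timeseries", "poses")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  for (col in intersect(c("timeseries", "poses", "centers"), names(m))) {
    missing <- !file.exists(m[[col]])
    if (any(missing))
      stop(sprintf("missing %s file(s): %s", col,
                   paste(m[[col]][missing], collapse = ", ")))
  }
  cnt <- table(m$participant)
  if (any(cnt != sessionsPerSubject))
    warning("participants with session count != ", sessionsPerSubject, ": ",
            paste(names(cnt)[cnt != sessionsPerSubject], collapse = ", "))
  m
}

#' Load sessions from a manifest
#'
#' @param manifest data.frame from [readManifest()].
#' @return list of [SessionRecord-class]
#' @export
loadSessions <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    X <- readTimeseriesTsv(row$timeseries)
    poses <- readPoseFile(row$poses)
    centers <- if (!is.null(row$centers) && !is.na(row$centers))
      as.matrix(read.table(row$centers, header = TRUE, sep = "\t"))
    else matrix(0, nrow(X), 3)
    new("SessionRecord", roiTimeseries = X, tr = row$tr, poses = poses,
        roiCenters = centers, covariates = list(),
        participantId = as.character(row$participant),
        sessionIndex = as.integer(row$session))
  })
}

#' Write / read a CoilField as NIfTI-1
#'
#' The voxel-to-mm affine is stored in the qform/sform; undefined voxels are
#' written as NaN. On read, the qform is preferred over the sform when both
#' are present.
#'
#' @param field a [CoilField-class].
#' @param path output `.nii` / `.nii.gz` path.
#' @return the path (write) or a [CoilField-class] (read)
#' @export
writeFieldNifti <- function(field, path) {
  sp <- sqrt(colSums(field@affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(field@values,
                         reference = list(pixdim = c(3, sp, rep(1, 4))))
  # RNifti xform maps 0-based voxel indices to world mm, as we do
  img <- RNifti::`sform<-`(img, structure(field@affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(field@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeFieldNifti
#' @export
readFieldNifti <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- matrix(as.numeric(RNifti::xform(img, useQuaternionFirst = TRUE)),
                   4, 4)
  v <- array(as.numeric(img), dim = dim(img))
  v[!is.finite(v)] <- NA_real_
  coilField(v, affine = affine)
}

#' Run configuration with a protocol-replication preset
#'
#' All analysis tunables with their defaults. `runConfig("replication")`
#' pins the split gap to 154 volumes, the 0.01--0.1 Hz band, linear
#' detrending, trilinear interpolation, a 50 mm FWD radius and direction
#' 1 -> 2 identification reporting.
#'
#' @param preset "default" or "replication".
#' @param ... overrides of individual fields.
#' @return named list of class `runConfig`
#' @export
runConfig <- function(preset = c("default", "replication"), ...) {
  preset <- match.arg(preset)
  cfg <- list(gapSeconds = 60, gapVolumes = NULL, lowHz = 0.01, highHz = 0.1,
              detrendOrder = 1L, interpolation = "trilinear",
              fwdRadiusMm = 50, nPermutations = 1000,
              qcSdThreshold = 3, qcSessionFraction = 0.10,
              direction = "1to2", seed = 1L, preset = preset)
  if (preset == "replication") cfg$gapVolumes <- 154L
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "runConfig")
}

#' Save / load a run configuration as YAML
#'
#' The serialization round-trips losslessly; every pipeline run writes its
#' effective configuration beside its outputs.
#'
#' @param config a [runConfig()] list.
#' @param path YAML file path.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname saveRunConfig
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$gapVolumes)) cfg$gapVolumes <- as.integer(cfg$gapVolumes)
  cfg$detrendOrder <- as.integer(cfg$detrendOrder)
  structure(cfg, class = "runConfig")
}
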