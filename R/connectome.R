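#' Full-session segment of a session
#'
#' @param session a [SessionRecord-class].
#' @return a [Segment-class] covering all volumes
#' @export
fullSegment <- function(session) {
  n <- ncol(session@roiTimeseries)
  new("Segment", data = session@roiTimeseries, tr = session@tr,
      parentId = sprintf("%s.%d", session@participantId,
                         session@sessionIndex),
      segmentIndex = "full", range = c(0L, n))
}

#' Split a session into two segments around a discarded middle gap
#'
#' Removes `gapSeconds` worth of volumes (rounded; or exactly `gapVolumes`
#' when given) from the middle of the timeseries and returns the two
#' remaining contiguous stretches as "split-session" segments. The gap is
#' centered so both segments have equal length; with an odd remainder the
#' first segment receives the extra volume.
#'
#' @param session a [SessionRecord-class].
#' @param gapSeconds gap duration in seconds (default 60).
#' @param gapVolumes gap length in volumes; overrides `gapSeconds` when
#'   given (the replication configuration pins 154 for TR 0.392 s sessions).
#' @param minSegment minimum acceptable segment length (default 64 volumes).
#' @return list of two [Segment-class] objects (`split-1`, `split-2`)
#' @examples
#' # a 2300-volume session with a 154-volume gap splits into
#' # [0, 1073) and [1227, 2300)
#' @export
splitSession <- function(session, gapSeconds = 60, gapVolumes = NULL,
                         minSegment = 64L) {
  n <- ncol(session@roiTimeseries)
  gap <- if (is.null(gapVolumes)) as.integer(round(gapSeconds / session@tr))
         else as.integer(gapVolumes)
  stopifnot(gap >= 0)
  rem <- n - gap
  if (rem < 2L * minSegment)
    stop(sprintf("session too short: %d volumes leave %d after a %d-volume gap (need >= %d)",
                 n, rem, gap, 2L * minSegment))
  len2 <- rem %/% 2L
  len1 <- rem - len2
  pid <- sprintf("%s.%d", session@participantId, session@sessionIndex)
  s1 <- new("Segment", data = session@roiTimeseries[, seq_len(len1),
                                                    drop = FALSE],
            tr = session@tr, parentId = pid, segmentIndex = "split-1",
            range = c(0L, len1))
  s2 <- new("Segment",
            data = session@roiTimeseries[, (len1 + gap + 1L):n, drop = FALSE],
            tr = session@tr, parentId = pid, segmentIndex = "split-2",
            range = c(len1 + gap, as.integer(n)))
  list(s1, s2)
}

#' Bandpass filter a segment to the functional-connectivity band
#'
#' Zero-phase (forward-backward) Butterworth bandpass of order 2 applied per
#' ROI after mean removal; output length equals input length. An FFT-mask
#' alternative (hard spectral window) is available for cross-checks.
#'
#' @param segment a [Segment-class] or an ROIs x volumes matrix.
#' @param lowHz,highHz passband edges in Hz (default 0.01--0.1).
#' @param tr repetition time in seconds (taken from the segment if omitted).
#' @param method "butterworth" (default) or "fft".
#' @return same type as the input, filtered
#' @export
bandpass <- function(segment, lowHz = 0.01, highHz = 0.1, tr = NULL,
                     method = c("butterworth", "fft")) {
  method <- match.arg(method)
  isSeg <- is(segment, "Segment")
  X <- if (isSeg) segment@data else segment
  if (isSeg) tr <- segment@tr
  if (is.null(tr)) stop("tr is required for matrix input")
  nyq <- 1 / (2 * tr)
  if (!(0 < lowHz && lowHz < highHz && highHz < nyq))
    stop(sprintf("invalid band [%g, %g] Hz for TR %g s (Nyquist %g Hz)",
                 lowHz, highHz, tr, nyq))
  X <- X - rowMeans(X)
  if (method == "butterworth") {
    bf <- signal::butter(2, c(lowHz, highHz) / nyq, type = "pass")
    Y <- t(apply(X, 1, function(x) signal::filtfilt(bf, x)))
  } else {
    n <- ncol(X)
    fr <- (seq_len(n) - 1) / (n * tr)
    fr <- pmin(fr, 1 / tr - fr)                 # two-sided frequency axis
    keep <- fr >= lowHz & fr <= highHz
    Y <- t(apply(X, 1, function(x) Re(stats::fft(stats::fft(x) * keep,
                                                 inverse = TRUE) / n)))
  }
  if (isSeg) {
    segment@data <- Y
    segment
  } else Y
}

#' Pearson connectome of a segment
#'
#' Functional connectivity of every ROI pair as the Pearson correlation of
#' their timeseries. Edges involving constant (zero-variance) series are
#' flagged NA and reported via a warning; the diagonal is 1.
#'
#' @param segment a [Segment-class] or an ROIs x volumes matrix.
#' @param roiIds integer labels for the rows (default 1..R).
#' @return a [Connectome-class]
#' @export
computeConnectome <- function(segment, roiIds = NULL) {
  X <- if (is(segment, "Segment")) segment@data else segment
  stopifnot(ncol(X) >= 3)
  if (is.null(roiIds)) roiIds <- seq_len(nrow(X))
  sds <- apply(X, 1, sd)
  flat <- sds == 0
  M <- suppressWarnings(cor(t(X)))
  if (any(flat)) {
    warning(sprintf("%d constant ROI series; their edges are flagged NA: %s",
                    sum(flat), paste(which(flat), collapse = ", ")))
    M[flat, ] <- NA_real_
    M[, flat] <- NA_real_
  }
  diag(M) <- 1
  M <- (M + t(M)) / 2
  new("Connectome", mat = M, roiIds = as.integer(roiIds))
}

#' ROI quality-control filter across sessions
#'
#' For each session, an ROI is an outlier when its mean signal intensity is
#' less than `sdThreshold` standard deviations below the mean across ROIs
#' (both mean and SD taken across ROIs within the session, on the raw
#' unfiltered series). An ROI is removed when it is an outlier in strictly
#' more than `sessionFraction` of the sessions.
#'
#' @param sessions list of [SessionRecord-class] objects (or ROIs x volumes
#'   matrices), all with the same ROI set.
#' @param sdThreshold outlier threshold in across-ROI SDs (default 3).
#' @param sessionFraction removal threshold on the outlier-session fraction;
#'   strictly greater than (default 0.10).
#' @return list of class `qcReport`: `perSession` (sessions x ROIs logical
#'   outlier matrix), `outlierFraction` (per ROI), `removedRois`,
#'   `retainedRois`, and the thresholds used
#' @export
qcRoiFilter <- function(sessions, sdThreshold = 3, sessionFraction = 0.10) {
  stopifnot(length(sessions) >= 2)
  getX <- function(s) if (is(s, "SessionRecord")) s@roiTimeseries else s
  nRoi <- nrow(getX(sessions[[1]]))
  per <- t(vapply(sessions, function(s) {
    m <- rowMeans(getX(s))
    m < mean(m) - sdThreshold * sd(m)
  }, logical(nRoi)))
  frac <- colMeans(per)
  removed <- which(frac > sessionFraction)
  structure(list(perSession = per, outlierFraction = frac,
                 removedRois = removed,
                 retainedRois = setdiff(seq_len(nRoi), removed),
                 sdThreshold = sdThreshold,
                 sessionFraction = sessionFraction),
            class = "qcReport")
}

#' @export
print.qcReport <- function(x, ...) {
  cat(sprintf("qcReport: %d sessions x %d ROIs; %d ROI(s) removed (> %.0f%% of sessions)\n",
              nrow(x$perSession), ncol(x$perSession), length(x$removedRois),
              100 * x$sessionFraction))
  if (length(x$removedRois))
    cat("  removed:", paste(x$removedRois, collapse = ", "), "\n")
  invisible(x)
}
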