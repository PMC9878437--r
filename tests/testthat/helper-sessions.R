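# Minimal SessionRecord around a given ROI x volumes matrix.
makeTestSession <- function(X, tr = 0.392, id = "T01", sessionIndex = 1L,
                            poses = NULL) {
  if (is.null(poses)) poses <- matrix(0, ncol(X), 6)
  new("SessionRecord", roiTimeseries = X, tr = tr, poses = poses,
      roiCenters = matrix(0, nrow(X), 3), covariates = list(),
      participantId = id, sessionIndex = sessionIndex)
}
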