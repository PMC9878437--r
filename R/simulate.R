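#' Random correlation matrix (Wishart-based)
#'
#' `cov2cor` of a Wishart draw with `df` degrees of freedom; smaller `df`
#' gives stronger off-diagonal structure.
#'
#' @param nRoi dimension.
#' @param df Wishart degrees of freedom (default `2 * nRoi`).
#' @param seed optional integer seed.
#' @return correlation matrix (unit diagonal, PSD)
#' @export
randomCorrelationMatrix <- function(nRoi, df = 2 * nRoi, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(rnorm(nRoi * df), nRoi, df)
  S <- tcrossprod(W) / df
  stats::cov2cor(S)
}

#' Network-structured random correlation matrix
#'
#' A single-factor-per-ROI model emulating resting-state network structure:
#' each ROI loads on one of `nNetworks` latent networks (loading uniform in
#' `loadRange`) plus a weak global factor, giving within-network
#' correlations of roughly 0.3--0.7 and near-zero between-network
#' correlations -- the magnitude structure of real functional connectomes.
#'
#' @param nRoi dimension.
#' @param nNetworks number of latent networks (default 8).
#' @param loadRange range of network loadings.
#' @param globalLoad loading on the shared global factor.
#' @param seed optional integer seed.
#' @return correlation matrix (unit diagonal, PSD)
#' @export
structuredCorrelationMatrix <- function(nRoi, nNetworks = 8,
                                        loadRange = c(0.55, 0.9),
                                        globalLoad = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  member <- sample.int(nNetworks, nRoi, replace = TRUE)
  load <- runif(nRoi, loadRange[1], loadRange[2])
  L <- matrix(0, nRoi, nNetworks + 1)
  L[cbind(seq_len(nRoi), member)] <- load
  L[, nNetworks + 1] <- globalLoad
  C <- tcrossprod(L)
  diag(C) <- 1
  C
}

#' Construct a subject specification for simulation
#'
#' The subject's trait connectome is a convex blend of a cohort-shared group
#' connectome and an individual random component:
#' `(1 - w) * group + w * individual`, with `w = individualWeight`. A convex
#' combination of correlation matrices is itself a valid correlation matrix.
#'
#' @param groupConnectome the cohort-shared correlation matrix.
#' @param individualWeight blend weight w in [0, 1] of the individual
#'   component (0 = all subjects identical).
#' @param headRadius head radius in mm.
#' @param covariates named list of session covariates.
#' @param seed optional integer seed (drives the individual component).
#' @return a [SubjectSpec-class]
#' @export
makeSubjectSpec <- function(groupConnectome, individualWeight = 0.3,
                            headRadius = 28, covariates = list(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nRoi <- nrow(groupConnectome)
  indiv <- structuredCorrelationMatrix(nRoi)
  trait <- (1 - individualWeight) * groupConnectome + individualWeight * indiv
  new("SubjectSpec", traitConnectome = trait, headRadius = headRadius,
      covariates = covariates)
}

# Symmetric square root via eigendecomposition (PSD input).
psdSqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-10) stop("matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate one scanning session
#'
#' Latent ROI signals are drawn as a stationary multivariate Gaussian whose
#' correlation is the subject's trait connectome blended with a
#' session-specific random perturbation of weight `stateNoise`. White
#' observation noise is added per ROI with variance chosen so that the ROI's
#' temporal SNR equals `tsnrCenter` times the coil-field value at the ROI's
#' posed scanner position (relative to the field value at the coil center).
#' Because the mean BOLD level is constant, attenuation of the observed
#' correlations scales with the product of the two ROIs' field values --
#' the mechanism by which head position couples SNR to measured functional
#' connectivity.
#'
#' Per-volume poses are the base pose plus slow within-session drift plus
#' occasional Poisson motion spikes. The drift is a stationary AR(1)
#' process (marginal SD 1 mm / 0.5 degrees at `jitterScale = 1`, correlation
#' time `driftTau` volumes): sleeping infants change posture slowly, so the
#' two split-segment reference poses of one session stay much closer
#' together than two different sessions' poses. Spike volumes additionally
#' receive a transient global intensity artifact, so high-motion sessions
#' have genuinely noisier connectomes. Noise variances are set from the
#' base pose (drift does not re-modulate the noise).
#'
#' @param subject a [SubjectSpec-class].
#' @param basePose a [HeadPose-class]: the session's reference pose.
#' @param field a [CoilField-class].
#' @param nVolumes number of volumes (>= 64).
#' @param tr repetition time in seconds.
#' @param stateNoise weight in [0, 1] of the session-specific perturbation of
#'   the trait connectome.
#' @param motionSpec list with `spikeRate` (expected spikes per volume),
#'   `spikeAmplitudeMm` (per-axis SD of a spike displacement) and
#'   `spikeArtifactSd` (SD of the transient intensity artifact).
#' @param roiCenters ROIs x 3 native-mm ROI centers; default a Fibonacci
#'   shell at 90% of the subject's head radius.
#' @param jitterScale multiplier on within-session pose drift (marginal SD
#'   1 mm / 0.5 degrees at 1).
#' @param driftTau AR(1) correlation time of the drift, in volumes
#'   (default `8 * nVolumes`: posture persists on the session timescale).
#' @param meanBold mean BOLD level (arbitrary units).
#' @param tsnrCenter target temporal SNR for an ROI at the coil center.
#' @param signalVarFracMax fraction of temporal variance that is latent
#'   signal at field value `fieldRefValue` (caps the noise floor).
#' @param fieldRefValue field value at which the signal fraction reaches
#'   `signalVarFracMax`; default the field's maximum. Cohort generation
#'   passes the highest field value any posed ROI attains, so the
#'   best-positioned ROI is nearly noise-free and attenuation scales down
#'   from there in proportion to the field.
#' @param seed integer seed; the output is a pure function of it.
#' @param participantId,sessionIndex identifiers stored in the record.
#' @return a [SessionRecord-class]
#' @export
simulateSession <- function(subject, basePose, field, nVolumes = 2300,
                            tr = 0.392, stateNoise = 0.25,
                            motionSpec = list(spikeRate = 0.0015,
                                              spikeAmplitudeMm = 3,
                                              spikeArtifactSd = 3),
                            roiCenters = NULL, jitterScale = 1,
                            driftTau = NULL, meanBold = 100, tsnrCenter = 40,
                            signalVarFracMax = 0.99, fieldRefValue = NULL,
                            seed = 1L, participantId = "S01",
                            sessionIndex = 1L) {
  stopifnot(nVolumes >= 64)
  validObject(subject)
  set.seed(seed)
  nRoi <- nrow(subject@traitConnectome)
  if (is.null(roiCenters))
    roiCenters <- fibonacciSphere(nRoi, 0.9 * subject@headRadius)
  if (is.null(driftTau)) driftTau <- 8 * nVolumes

  # session-state blend of the trait connectome
  Csess <- if (stateNoise > 0) {
    (1 - stateNoise) * subject@traitConnectome +
      stateNoise * structuredCorrelationMatrix(nRoi)
  } else subject@traitConnectome
  L <- psdSqrt(Csess)
  latent <- L %*% matrix(rnorm(nRoi * nVolumes), nRoi, nVolumes)

  # SNR geometry: tSNR_r = tsnrCenter * f_r / f0
  posed <- applyPose(basePose, roiCenters)
  fr <- sampleField(field, posed)
  if (any(is.na(fr)))
    stop("ROIs posed outside field coverage: ",
         paste(which(is.na(fr)), collapse = ", "))
  f0 <- sampleField(field, c(0, 0, 0))
  if (is.na(f0)) stop("field is undefined at the coil center")
  if (is.null(fieldRefValue))
    fieldRefValue <- max(field@values, na.rm = TRUE)
  sdTot <- meanBold * f0 / (tsnrCenter * fr)
  sdSig <- sqrt(signalVarFracMax) * meanBold * f0 /
    (tsnrCenter * fieldRefValue)
  sdNoise <- sqrt(pmax(sdTot^2 - sdSig^2, (0.05 * sdSig)^2))

  X <- meanBold + sdSig * latent +
    sdNoise * matrix(rnorm(nRoi * nVolumes), nRoi, nVolumes)

  # per-volume poses: base + slow AR(1) postural drift
  poses <- matrix(rep(poseToRow(basePose), each = nVolumes), nVolumes, 6)
  if (jitterScale > 0) {
    phi <- exp(-1 / driftTau)
    drift <- matrix(0, nVolumes, 6)
    sdDrift <- c(rep(0.5 * pi / 180, 3), rep(1, 3)) * jitterScale
    drift[1, ] <- rnorm(6, 0, sdDrift)
    innov <- matrix(rnorm(6 * (nVolumes - 1)), nVolumes - 1, 6) *
      rep(sdDrift * sqrt(1 - phi^2), each = nVolumes - 1)
    for (t in 2:nVolumes) drift[t, ] <- phi * drift[t - 1, ] + innov[t - 1, ]
    poses <- poses + drift
  }
  nSpike <- rpois(1, motionSpec$spikeRate * nVolumes)
  if (nSpike > 0) {
    at <- sample.int(nVolumes, min(nSpike, nVolumes))
    poses[at, 4:6] <- poses[at, 4:6] +
      matrix(rnorm(3 * length(at), 0, motionSpec$spikeAmplitudeMm),
             length(at), 3)
    art <- if (is.null(motionSpec$spikeArtifactSd)) 3 else
      motionSpec$spikeArtifactSd
    X[, at] <- X[, at] + matrix(rnorm(nRoi * length(at), 0, art),
                                nRoi, length(at))
  }

  new("SessionRecord", roiTimeseries = X, tr = tr, poses = poses,
      roiCenters = roiCenters, covariates = subject@covariates,
      participantId = participantId, sessionIndex = as.integer(sessionIndex))
}

#' Default cohort configuration
#'
#' The defaults emulate the study conditions the analysis targets: 44
#' subjects scanned twice (preterm and term), 2300 volumes at TR 0.392 s,
#' between-session repositioning spanning the observed centroid ranges, and
#' within-session pose jitter of SD 1 mm / 0.5 degrees.
#'
#' @param nRoi number of cortical ROIs (scaled-down parcellation).
#' @param nVolumes volumes per session.
#' @param tr repetition time (s).
#' @param individualWeight weight of the individual trait component.
#' @param stateNoise session-state perturbation weight.
#' @param poseConsistency fraction in [0, 1] of the between-session
#'   repositioning that is subject-specific (a consistent resting position)
#'   rather than redrawn each session.
#' @param repositioning "between" (redraw each session) or "none" (each
#'   subject keeps one pose across sessions).
#' @param jitterScale within-session pose jitter multiplier.
#' @param headRadiusMean,headRadiusSd head-size distribution (mm).
#' @param tsnrCenter temporal SNR at the coil center.
#' @param signalVarFracMax latent-signal variance fraction at the highest
#'   field value.
#' @param meanBold mean BOLD level.
#' @param motionSpec motion-spike specification (see [simulateSession()]).
#' @param field a [CoilField-class], or NULL for the default coil field.
#' @return named list of configuration values
#' @export
cohortConfig <- function(nRoi = 100, nVolumes = 2300, tr = 0.392,
                         individualWeight = 0.3, stateNoise = 0.5,
                         poseConsistency = 0.3,
                         repositioning = c("between", "none"),
                         jitterScale = 1, headRadiusMean = 28,
                         headRadiusSd = 1.5, tsnrCenter = 40,
                         signalVarFracMax = 0.99, meanBold = 100,
                         motionSpec = list(spikeRate = 0.0015,
                                           spikeAmplitudeMm = 3),
                         field = NULL) {
  list(nRoi = nRoi, nVolumes = nVolumes, tr = tr,
       individualWeight = individualWeight, stateNoise = stateNoise,
       poseConsistency = poseConsistency,
       repositioning = match.arg(repositioning), jitterScale = jitterScale,
       headRadiusMean = headRadiusMean, headRadiusSd = headRadiusSd,
       tsnrCenter = tsnrCenter, signalVarFracMax = signalVarFracMax,
       meanBold = meanBold, motionSpec = motionSpec, field = field)
}

#' Generate a synthetic cohort with a ground-truth ledger
#'
#' Draws per-subject trait connectomes (shared group component plus an
#' individual component), head sizes and covariates; assigns each session a
#' between-session base pose (partially consistent within subject); and
#' simulates every session's ROI timeseries against the coil field. The
#' returned ledger records every planted quantity for parameter-recovery
#' tests.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param sessionsPerSubject sessions per subject.
#' @param config a [cohortConfig()] list.
#' @param seed integer master seed; all randomness derives from it.
#' @return list with `sessions` (list of [SessionRecord-class], ordered by
#'   subject then session), `ledger` (per-subject truth: subject specs, base
#'   poses, per-ROI true SNR per session, covariate table), `field`, and
#'   `config`
#' @export
makeCohort <- function(nSubjects = 44, sessionsPerSubject = 2,
                       config = cohortConfig(), seed = 1L) {
  stopifnot(nSubjects >= 2)
  field <- config$field
  if (is.null(field)) field <- makeCoilField()
  f0 <- sampleField(field, c(0, 0, 0))

  set.seed(childSeed(seed, 1))
  group <- structuredCorrelationMatrix(config$nRoi)

  ids <- sprintf("S%03d", seq_len(nSubjects))
  set.seed(childSeed(seed, 2))
  headRadius <- rnorm(nSubjects, config$headRadiusMean, config$headRadiusSd)
  age1 <- runif(nSubjects, 29, 37)            # weeks PMA at first session
  interval <- runif(nSubjects, 4, 12)         # weeks between sessions
  ofc <- 2 * pi * headRadius / 10             # cm, tied to head radius
  uSubj <- matrix(runif(6 * nSubjects), nSubjects, 6)

  # shared cortical ROI template: ellipsoidal shell (LR x PA x SI axes)
  # with per-ROI radial scatter, scaled by each subject's head radius
  set.seed(childSeed(seed, 3))
  unitShell <- fibonacciSphere(config$nRoi, 1)
  template <- unitShell * matrix(rep(c(0.85, 1.05, 0.8), each = config$nRoi),
                                 ncol = 3) *
    runif(config$nRoi, 0.85, 1.05) * 0.9

  sessions <- vector("list", nSubjects * sessionsPerSubject)
  subjects <- vector("list", nSubjects)
  basePoses <- vector("list", nSubjects)
  trueSnr <- vector("list", nSubjects)
  covTab <- data.frame(participant = ids, headRadius = headRadius,
                       ofc = ofc, age1 = age1, interval = interval)

  # draw all base poses first: the signal-fraction reference is the highest
  # field value any posed ROI attains across the cohort
  for (s in seq_len(nSubjects)) {
    basePoses[[s]] <- vector("list", sessionsPerSubject)
    for (e in seq_len(sessionsPerSubject)) {
      set.seed(childSeed(seed, 10000 + 10 * s + e))
      uSess <- runif(6)
      u <- if (config$repositioning == "none") uSubj[s, ] else
        config$poseConsistency * uSubj[s, ] +
          (1 - config$poseConsistency) * uSess
      basePoses[[s]][[e]] <- poseFromQuantiles(u)
    }
  }
  fRef <- max(vapply(seq_len(nSubjects), function(s)
    max(vapply(basePoses[[s]], function(p) {
      fr <- sampleField(field, applyPose(p, template * headRadius[s]))
      if (any(is.na(fr)))
        stop("ROIs posed outside field coverage for subject ", ids[s])
      max(fr)
    }, 0)), 0))

  k <- 0L
  for (s in seq_len(nSubjects)) {
    covs <- list(age = age1[s] + (seq_len(sessionsPerSubject) - 1) *
                   interval[s], ofc = ofc[s], interval = interval[s])
    subjects[[s]] <- makeSubjectSpec(group, config$individualWeight,
                                     headRadius = headRadius[s],
                                     covariates = covs,
                                     seed = childSeed(seed, 100 + s))
    trueSnr[[s]] <- vector("list", sessionsPerSubject)
    for (e in seq_len(sessionsPerSubject)) {
      k <- k + 1L
      pose <- basePoses[[s]][[e]]
      sessions[[k]] <- simulateSession(
        subjects[[s]], pose, field, nVolumes = config$nVolumes,
        tr = config$tr, stateNoise = config$stateNoise,
        motionSpec = config$motionSpec,
        roiCenters = template * headRadius[s],
        jitterScale = config$jitterScale,
        meanBold = config$meanBold, tsnrCenter = config$tsnrCenter,
        signalVarFracMax = config$signalVarFracMax, fieldRefValue = fRef,
        seed = childSeed(seed, 20000 + 10 * s + e),
        participantId = ids[s], sessionIndex = e)
      posed <- applyPose(pose, sessions[[k]]@roiCenters)
      trueSnr[[s]][[e]] <- config$tsnrCenter * sampleField(field, posed) / f0
    }
  }
  list(sessions = sessions,
       ledger = list(ids = ids, subjects = subjects, basePoses = basePoses,
                     trueSnr = trueSnr, covariates = covTab,
                     groupConnectome = group, seed = seed),
       field = field, config = config)
}
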