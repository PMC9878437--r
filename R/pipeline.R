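#' Full analysis of a (synthetic or loaded) cohort
#'
#' Runs the complete chain on a set of sessions: ROI quality control;
#' full-session and split-session segmentation with bandpass filtering and
#' Pearson connectomes; head-pose SNR profiles (SNR-group) at the segment
#' reference volumes; representational similarity matrices and
#' identification for connectomes and for SNR profiles, across sessions and
#' within sessions; and the connectome-stability regressions.
#'
#' @param cohort a [makeCohort()] result, or a list with `sessions` (list of
#'   [SessionRecord-class]) and optionally `field` (a [CoilField-class];
#'   required for the SNR stages).
#' @param config a [runConfig()] list.
#' @return list of class `cohortAnalysis` with components `qc`,
#'   `edges` (full/split edge matrices), `snr` (profiles), `rsm`,
#'   `identification`, `summary`, `stability`, `fwd`, `config`
#' @export
analyzeCohort <- function(cohort, config = runConfig()) {
  sessions <- cohort$sessions
  field <- cohort$field
  qc <- qcRoiFilter(sessions, config$qcSdThreshold, config$qcSessionFraction)
  keep <- qc$retainedRois

  ids <- vapply(sessions, function(s) s@participantId, character(1))
  ses <- vapply(sessions, function(s) s@sessionIndex, integer(1))
  uids <- unique(ids)
  nSes <- max(ses)

  perSession <- lapply(sessions, function(s) {
    X <- s@roiTimeseries[keep, , drop = FALSE]
    sub <- new("SessionRecord", roiTimeseries = X, tr = s@tr,
               poses = s@poses, roiCenters = s@roiCenters[keep, , drop = FALSE],
               covariates = s@covariates, participantId = s@participantId,
               sessionIndex = s@sessionIndex)
    full <- fullSegment(sub)
    splits <- splitSession(sub, gapSeconds = config$gapSeconds,
                           gapVolumes = config$gapVolumes)
    connFull <- computeConnectome(bandpass(full, config$lowHz, config$highHz),
                                  roiIds = keep)
    connSplit <- lapply(splits, function(sg)
      computeConnectome(bandpass(sg, config$lowHz, config$highHz),
                        roiIds = keep))
    fwd <- framewiseDisplacement(sub, config$fwdRadiusMm)
    out <- list(connFull = connFull, connSplit = connSplit, fwd = fwd,
                tsnr = computeTsnr(X, config$detrendOrder))
    if (!is.null(field)) {
      poseFull <- poseAtReferenceVolume(sub@poses, full)
      poseSplit <- lapply(splits, function(sg)
        poseAtReferenceVolume(sub@poses, sg))
      out$snrFull <- snrProfileFromCenters(field, sub@roiCenters, poseFull)
      out$snrSplit <- lapply(poseSplit, function(p)
        snrProfileFromCenters(field, sub@roiCenters, p))
    }
    out
  })

  bySes <- function(e) which(ses == e)[match(uids, ids[ses == e])]
  rsm <- list()
  if (nSes >= 2) {
    i1 <- bySes(1); i2 <- bySes(2)
    rsm$acrossConn <- computeRsm(
      lapply(perSession[i1], function(p) edgeVector(p$connFull)),
      lapply(perSession[i2], function(p) edgeVector(p$connFull)), uids)
    if (!is.null(field))
      rsm$acrossSnr <- computeRsm(
        lapply(perSession[i1], function(p) p$snrFull),
        lapply(perSession[i2], function(p) p$snrFull), uids)
  }
  rsm$withinConn <- lapply(seq_len(nSes), function(e) {
    ii <- bySes(e)
    computeRsm(lapply(perSession[ii], function(p) edgeVector(p$connSplit[[1]])),
               lapply(perSession[ii], function(p) edgeVector(p$connSplit[[2]])),
               uids)
  })
  if (!is.null(field))
    rsm$withinSnr <- lapply(seq_len(nSes), function(e) {
      ii <- bySes(e)
      computeRsm(lapply(perSession[ii], function(p) p$snrSplit[[1]]),
                 lapply(perSession[ii], function(p) p$snrSplit[[2]]), uids)
    })

  idf <- function(r) identifyParticipants(r, config$direction)
  identification <- list()
  summary <- list()
  if (!is.null(rsm$acrossConn)) {
    identification$acrossConn <- idf(rsm$acrossConn)
    summary$acrossConn <- withinBetweenSummary(rsm$acrossConn)
  }
  identification$withinConn <- lapply(rsm$withinConn, idf)
  summary$withinConn <- lapply(rsm$withinConn, withinBetweenSummary)
  if (!is.null(field)) {
    if (!is.null(rsm$acrossSnr)) {
      identification$acrossSnr <- idf(rsm$acrossSnr)
      summary$acrossSnr <- withinBetweenSummary(rsm$acrossSnr)
    }
    identification$withinSnr <- lapply(rsm$withinSnr, idf)
    summary$withinSnr <- lapply(rsm$withinSnr, withinBetweenSummary)
  }

  # stability regressions (need two sessions and the covariate ledger)
  stability <- NULL
  if (nSes >= 2 && !is.null(field) && !is.null(cohort$ledger)) {
    cov <- cohort$ledger$covariates
    cov <- cov[match(uids, cov$participant), ]
    i1 <- bySes(1); i2 <- bySes(2)
    meanSnrFull <- (vapply(perSession[i1], function(p) mean(p$snrFull),
                           0) +
                    vapply(perSession[i2], function(p) mean(p$snrFull), 0)) / 2
    meanFwdFull <- (vapply(perSession[i1], function(p) p$fwd$mean, 0) +
                    vapply(perSession[i2], function(p) p$fwd$mean, 0)) / 2
    eq3 <- tryCatch(stabilityRegression(
      diag(rsm$acrossConn@mat),
      data.frame(snr = meanSnrFull, fwd = meanFwdFull,
                 interval = cov$interval, age = cov$age1, ofc = cov$ofc),
      model = "full_session"), error = function(e) {
        warning("full-session stability model skipped: ",
                conditionMessage(e))
        NULL
      })
    stabSplit <- unlist(lapply(seq_len(nSes), function(e)
      diag(rsm$withinConn[[e]]@mat)))
    snrSplit <- unlist(lapply(seq_len(nSes), function(e)
      vapply(perSession[bySes(e)], function(p)
        mean(c(mean(p$snrSplit[[1]]), mean(p$snrSplit[[2]]))), 0)))
    fwdSplit <- unlist(lapply(seq_len(nSes), function(e)
      vapply(perSession[bySes(e)], function(p) p$fwd$mean, 0)))
    eq4 <- tryCatch(stabilityRegression(stabSplit,
                               data.frame(snr = snrSplit, fwd = fwdSplit),
                               model = "split_session"),
                    error = function(e) {
                      warning("split-session stability model skipped: ",
                              conditionMessage(e))
                      NULL
                    })
    stability <- list(fullSession = eq3, splitSession = eq4)
  }

  structure(list(qc = qc, perSession = perSession, ids = ids,
                 sessionIndex = ses, participants = uids, rsm = rsm,
                 identification = identification, summary = summary,
                 stability = stability, config = config),
            class = "cohortAnalysis")
}

#' @export
print.cohortAnalysis <- function(x, ...) {
  cat(sprintf("cohortAnalysis: %d participants, %d sessions, %d retained ROIs\n",
              length(x$participants), length(x$ids),
              length(x$qc$retainedRois)))
  if (!is.null(x$identification$acrossConn))
    cat(sprintf("  across-session connectome ID: %.0f%%\n",
                100 * x$identification$acrossConn$rate))
  w <- vapply(x$identification$withinConn, function(i) i$rate, 0)
  cat(sprintf("  within-session connectome ID: %s\n",
              paste(sprintf("%.0f%%", 100 * w), collapse = ", ")))
  invisible(x)
}

# Mean identification rate over the within-session RSMs.
meanWithinRate <- function(analysis, what = "withinConn") {
  mean(vapply(analysis$identification[[what]], function(i) i$rate, 0))
}

#' End-to-end demonstration of the head-position confound
#'
#' Generates a synthetic two-session cohort under the default study
#' conditions, runs full- and split-session fingerprinting on connectomes
#' and on head-pose SNR profiles, the predictor-comparison regression in
#' both segment regimes, and the connectome-stability models; optionally
#' writes a markdown report.
#'
#' @param seed master seed.
#' @param nSubjects number of subjects (default 44).
#' @param cohortCfg a [cohortConfig()] list.
#' @param config a [runConfig()] list.
#' @param reportPath optional path for a markdown report.
#' @return list of class `demoReport`: `rates` (the four identification
#'   rates), `summaries`, `eq2` (full and split), `stability`, `analysis`
#' @export
demoConfound <- function(seed = 1L, nSubjects = 44,
                         cohortCfg = cohortConfig(), config = runConfig(),
                         reportPath = NULL) {
  cohort <- makeCohort(nSubjects, 2, cohortCfg, seed = seed)
  an <- analyzeCohort(cohort, config)

  i1 <- which(an$sessionIndex == 1)[match(an$participants,
                                          an$ids[an$sessionIndex == 1])]
  i2 <- which(an$sessionIndex == 2)[match(an$participants,
                                          an$ids[an$sessionIndex == 2])]
  fullE <- lapply(an$perSession, function(p) edgeVector(p$connFull))
  snrF <- lapply(an$perSession, function(p) p$snrFull)
  eq2full12 <- predictorComparison(do.call(rbind, fullE[i1]),
                                   do.call(rbind, fullE[i2]),
                                   do.call(rbind, snrF[i1]))
  eq2full21 <- predictorComparison(do.call(rbind, fullE[i2]),
                                   do.call(rbind, fullE[i1]),
                                   do.call(rbind, snrF[i2]))
  splitPair <- function(ii, a, b) {
    predictorComparison(
      do.call(rbind, lapply(an$perSession[ii], function(p)
        edgeVector(p$connSplit[[a]]))),
      do.call(rbind, lapply(an$perSession[ii], function(p)
        edgeVector(p$connSplit[[b]]))),
      do.call(rbind, lapply(an$perSession[ii], function(p) p$snrSplit[[a]])))
  }
  eq2split <- list(splitPair(i1, 1, 2), splitPair(i1, 2, 1),
                   splitPair(i2, 1, 2), splitPair(i2, 2, 1))

  rates <- c(connAcross = an$identification$acrossConn$rate,
             connWithin = meanWithinRate(an, "withinConn"),
             snrAcross = an$identification$acrossSnr$rate,
             snrWithin = meanWithinRate(an, "withinSnr"))
  out <- structure(list(
    rates = rates, summaries = an$summary,
    eq2 = list(
      fullSession = list(
        directions = list(eq2full12, eq2full21),
        meanBetaSnr = mean(c(eq2full12$meanBetaSnr, eq2full21$meanBetaSnr)),
        meanBetaFc = mean(c(eq2full12$meanBetaFc, eq2full21$meanBetaFc))),
      splitSession = list(
        directions = eq2split,
        meanBetaSnr = mean(vapply(eq2split, function(e) e$meanBetaSnr, 0)),
        meanBetaFc = mean(vapply(eq2split, function(e) e$meanBetaFc, 0)))),
    stability = an$stability, analysis = an, seed = seed),
    class = "demoReport")
  if (!is.null(reportPath)) writeDemoReport(out, reportPath)
  out
}

#' @export
print.demoReport <- function(x, ...) {
  cat("head-position confound demonstration\n")
  cat(sprintf("  connectome ID: within %.0f%%, across %.0f%%\n",
              100 * x$rates["connWithin"], 100 * x$rates["connAcross"]))
  cat(sprintf("  SNR-only ID:   within %.0f%%, across %.0f%%\n",
              100 * x$rates["snrWithin"], 100 * x$rates["snrAcross"]))
  cat(sprintf("  predictor comparison (split): beta_SNR %.3f, beta_FC %.3f\n",
              x$eq2$splitSession$meanBetaSnr, x$eq2$splitSession$meanBetaFc))
  invisible(x)
}

#' Write a markdown report for a confound demonstration
#'
#' @param report a [demoConfound()] result.
#' @param path output markdown path.
#' @export
writeDemoReport <- function(report, path) {
  r <- report$rates
  s <- report$summaries
  ln <- c(
    "# Head-position confound demonstration (synthetic cohort)",
    "",
    sprintf("Master seed: %d", report$seed),
    "",
    "## Identification rates",
    "",
    "| profile | within session | across sessions |",
    "|---|---|---|",
    sprintf("| connectome | %.1f%% | %.1f%% |", 100 * r["connWithin"],
            100 * r["connAcross"]),
    sprintf("| SNR-group (pose only) | %.1f%% | %.1f%% |",
            100 * r["snrWithin"], 100 * r["snrAcross"]),
    "",
    "## Within- vs between-participant Spearman (connectomes)",
    "",
    sprintf("- across sessions: within %.3f, between %.3f",
            s$acrossConn$within, s$acrossConn$between),
    sprintf("- within session: within %.3f, between %.3f",
            mean(vapply(s$withinConn, function(z) z$within, 0)),
            mean(vapply(s$withinConn, function(z) z$between, 0))),
    "",
    "## Predictor comparison (standardized coefficients)",
    "",
    sprintf("- full-session segments: mean beta_SNR %.3f, mean beta_FC %.3f",
            report$eq2$fullSession$meanBetaSnr,
            report$eq2$fullSession$meanBetaFc),
    sprintf("- split-session segments: mean beta_SNR %.3f, mean beta_FC %.3f",
            report$eq2$splitSession$meanBetaSnr,
            report$eq2$splitSession$meanBetaFc),
    "")
  if (!is.null(report$stability)) {
    cf3 <- report$stability$fullSession$coefficients
    cf4 <- report$stability$splitSession$coefficients
    ln <- c(ln, "## Connectome-stability models", "",
            sprintf("- full-session: %s",
                    paste(sprintf("%s %+.2f", names(cf3), cf3),
                          collapse = ", ")),
            sprintf("- split-session: %s",
                    paste(sprintf("%s %+.2f", names(cf4), cf4),
                          collapse = ", ")),
            "")
  }
  writeLines(ln, path)
  invisible(path)
}

#' Run the pipeline on a manifest or cohort and write results
#'
#' Orchestrates the full analysis and writes its outputs (QC report,
#' identification tables, similarity summaries, stability models and the
#' effective configuration) to a result directory. Any stage error aborts
#' with the stage name.
#'
#' @param x a cohort list (from [makeCohort()]) or a manifest data.frame
#'   (from [readManifest()]).
#' @param config a [runConfig()] list.
#' @param outDir output directory.
#' @param field optional [CoilField-class] for the SNR stages when `x` is a
#'   manifest.
#' @return the `cohortAnalysis`, invisibly
#' @export
runPipeline <- function(x, config = runConfig(), outDir, field = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cohort <- if (is.data.frame(x)) {
    sessions <- stage("load", loadSessions(x))
    list(sessions = sessions, field = field)
  } else x
  an <- stage("analysis", analyzeCohort(cohort, config))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage("write", {
    saveRunConfig(config, file.path(outDir, "config.yaml"))
    jsonlite::write_json(
      list(removedRois = an$qc$removedRois,
           outlierFraction = an$qc$outlierFraction),
      file.path(outDir, "qc_report.json"), digits = NA, auto_unbox = TRUE)
    rates <- lapply(an$identification, function(v) {
      if (inherits(v, "identification")) v$rate
      else vapply(v, function(i) i$rate, 0)
    })
    jsonlite::write_json(rates, file.path(outDir, "identification.json"),
                         digits = NA, auto_unbox = TRUE)
    for (nm in names(an$rsm)) {
      obj <- an$rsm[[nm]]
      objs <- if (is.list(obj)) obj else list(obj)
      for (k in seq_along(objs))
        write.table(similarityMatrix(objs[[k]]),
                    file.path(outDir, sprintf("rsm_%s_%d.tsv", nm, k)),
                    sep = "\t", quote = FALSE)
    }
    if (!is.null(an$stability))
      jsonlite::write_json(
        lapply(an$stability, function(m)
          list(coefficients = as.list(m$coefficients),
               pValues = as.list(m$pValues), n = m$n)),
        file.path(outDir, "stability_models.json"), digits = NA,
        auto_unbox = TRUE)
  })
  invisible(an)
}
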