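#' Representational similarity matrix across segments
#'
#' Entry (p, q) is the Spearman rank correlation between participant p's
#' segment-1 feature vector and participant q's segment-2 vector. Feature
#' vectors are connectome edge vectors or SNR profiles. Indices that are
#' undefined (NA) in any vector of either segment are dropped
#' pairwise-consistently: one shared index set for every pair.
#'
#' @param vectorsSeg1,vectorsSeg2 per-participant feature vectors: a list of
#'   numeric vectors or a P x E matrix (rows = participants), with matching
#'   participant order.
#' @param ids participant identifiers (default names or P1..Pn).
#' @return an [RSM-class]: rows are segment-1 owners, columns segment-2
#' @export
computeRsm <- function(vectorsSeg1, vectorsSeg2, ids = NULL) {
  asMat <- function(v) {
    if (is.list(v)) do.call(rbind, v) else as.matrix(v)
  }
  V1 <- asMat(vectorsSeg1)
  V2 <- asMat(vectorsSeg2)
  if (ncol(V1) != ncol(V2)) stop("segment vectors differ in length")
  if (nrow(V1) != nrow(V2)) stop("segments must cover the same participants")
  if (is.null(ids)) {
    ids <- rownames(V1)
    if (is.null(ids)) ids <- sprintf("P%02d", seq_len(nrow(V1)))
  }
  keep <- colSums(is.na(V1)) == 0 & colSums(is.na(V2)) == 0
  if (!any(keep)) stop("no defined feature indices shared by all vectors")
  R1 <- apply(V1[, keep, drop = FALSE], 1, rank)   # E' x P
  R2 <- apply(V2[, keep, drop = FALSE], 1, rank)
  M <- cor(R1, R2)
  new("RSM", mat = M, ids = ids)
}

#' Identification ("fingerprinting") from an RSM
#'
#' For each target, the database entry with the highest similarity is the
#' best match; a match occurs when it belongs to the same participant.
#' Direction `"1to2"` takes segment-1 vectors as targets (rows) against the
#' segment-2 database (columns); `"2to1"` the reverse. Exact ties involving
#' the self similarity are never broken in favour of self: they are counted
#' as non-matches and reported.
#'
#' @param rsm an [RSM-class].
#' @param direction "1to2" (default) or "2to1".
#' @return list of class `identification`: `rate`, `matches`, `n`,
#'   `bestMatch` (id per target), `selfRank` (rank of the self similarity,
#'   1 = best), `ties` (targets whose top similarity was tied with self),
#'   `direction`
#' @export
identifyParticipants <- function(rsm, direction = c("1to2", "2to1")) {
  direction <- match.arg(direction)
  M <- rsm@mat
  if (direction == "2to1") M <- t(M)
  P <- nrow(M)
  best <- integer(P)
  selfRank <- integer(P)
  tied <- logical(P)
  matched <- logical(P)
  for (p in seq_len(P)) {
    row <- M[p, ]
    top <- max(row)
    winners <- which(row == top)
    best[p] <- winners[1]
    selfRank[p] <- rank(-row, ties.method = "min")[p]
    if (length(winners) > 1 && p %in% winners) {
      tied[p] <- TRUE
      matched[p] <- FALSE          # conservative: ties never credit self
    } else {
      matched[p] <- identical(winners, p)
    }
  }
  structure(list(rate = mean(matched), matches = sum(matched), n = P,
                 bestMatch = rsm@ids[best], selfRank = selfRank,
                 ties = rsm@ids[tied], direction = direction),
            class = "identification")
}

#' @export
print.identification <- function(x, ...) {
  cat(sprintf("identification (%s): %d/%d matched (%.1f%%)%s\n",
              x$direction, x$matches, x$n, 100 * x$rate,
              if (length(x$ties)) sprintf(", %d tie(s)", length(x$ties))
              else ""))
  invisible(x)
}

#' Within- and between-participant similarity summary
#'
#' The diagonal of the RSM is the within-participant (stability) similarity;
#' the off-diagonal entries (both triangles of the asymmetric matrix) are
#' the between-participant shared similarity.
#'
#' @param rsm an [RSM-class].
#' @return list with `within` and `between` mean Spearman correlations
#' @export
withinBetweenSummary <- function(rsm) {
  M <- rsm@mat
  off <- M[row(M) != col(M)]
  list(within = mean(diag(M)), between = mean(off))
}

#' Connectome stabilities (RSM diagonal)
#'
#' @param rsm an [RSM-class].
#' @return named numeric vector of within-participant Spearman correlations
#' @export
connectomeStability <- function(rsm) {
  setNames(diag(rsm@mat), rsm@ids)
}
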