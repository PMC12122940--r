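#' Geometric criteria for a TS-like conformation
#'
#' A frame is transition-state-like for SN2 methyl transfer when the
#' target-lysine Nepsilon to methyl-carbon distance is strictly below
#' \code{dMax}, the nucleophilic attack angle (Cdelta-Nepsilon bond vs
#' the Nepsilon to methyl-carbon direction) lies within
#' \code{attackCenter +/- attackTol}, and the Nepsilon / methyl-C /
#' sulfur transfer axis is linear within
#' \code{linearCenter +/- linearTol}. Angle bounds are inclusive, the
#' distance bound is strict.
#'
#' @param dMax Angstrom, default 4.
#' @param attackCenter,attackTol degrees, defaults 109 and 30.
#' @param linearCenter,linearTol degrees, defaults 180 and 30.
#' @return list of class \code{TSCriteria}.
#' @export
tsCriteria <- function(dMax = 4, attackCenter = 109, attackTol = 30,
                       linearCenter = 180, linearTol = 30) {
  if (dMax <= 0) stop("dMax must be > 0")
  if (attackTol <= 0 || linearTol <= 0) stop("tolerances must be > 0")
  structure(list(dMax = dMax, attackCenter = attackCenter,
                 attackTol = attackTol, linearCenter = linearCenter,
                 linearTol = linearTol), class = "TSCriteria")
}

vecAngleDeg <- function(ux, uy, uz, vx, vy, vz) {
  num <- ux * vx + uy * vy + uz * vz
  den <- sqrt((ux^2 + uy^2 + uz^2) * (vx^2 + vy^2 + vz^2))
  if (any(den == 0)) stop("coincident points: angle undefined")
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

#' Reaction geometry of every frame
#'
#' Computes, per frame, the Nepsilon to methyl-carbon distance \code{d},
#' the attack angle \code{thetaAttack} at Nepsilon between the
#' Cdelta-Nepsilon bond and the Nepsilon to methyl-carbon direction, and
#' the transfer-axis angle \code{thetaLinear} at the methyl carbon
#' between Nepsilon and the sulfur.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param atomMap atom map from \code{\link{resolveAtomMap}}; resolved
#'   automatically when \code{NULL}.
#' @return data.frame with columns \code{frame}, \code{d},
#'   \code{thetaAttack}, \code{thetaLinear}.
#' @export
ensembleGeometry <- function(ensemble, atomMap = NULL) {
  m <- atomMap %||% resolveAtomMap(ensemble)
  co <- ensemble@coords
  g <- function(i, k) co[i, k, ]
  dx <- g(m$methylC, 1L) - g(m$nz, 1L)
  dy <- g(m$methylC, 2L) - g(m$nz, 2L)
  dz <- g(m$methylC, 3L) - g(m$nz, 3L)
  d <- sqrt(dx^2 + dy^2 + dz^2)
  cdx <- g(m$cd, 1L) - g(m$nz, 1L)
  cdy <- g(m$cd, 2L) - g(m$nz, 2L)
  cdz <- g(m$cd, 3L) - g(m$nz, 3L)
  thetaAttack <- vecAngleDeg(cdx, cdy, cdz, dx, dy, dz)
  sx <- g(m$sulfur, 1L) - g(m$methylC, 1L)
  sy <- g(m$sulfur, 2L) - g(m$methylC, 2L)
  sz <- g(m$sulfur, 3L) - g(m$methylC, 3L)
  thetaLinear <- vecAngleDeg(-dx, -dy, -dz, sx, sy, sz)
  data.frame(frame = seq_len(nFrames(ensemble)), d = d,
             thetaAttack = thetaAttack, thetaLinear = thetaLinear)
}

#' Reaction geometry of one frame
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param frame 1-based frame index.
#' @param atomMap see \code{\link{ensembleGeometry}}.
#' @return list with \code{d}, \code{thetaAttack}, \code{thetaLinear}.
#' @export
frameGeometry <- function(ensemble, frame, atomMap = NULL) {
  g <- ensembleGeometry(ensemble, atomMap)
  as.list(g[g$frame == frame, c("d", "thetaAttack", "thetaLinear")])
}

#' Classify geometries as TS-like
#'
#' @param geometry data.frame from \code{\link{ensembleGeometry}} (or a
#'   list with the same fields for one frame).
#' @param criteria a \code{\link{tsCriteria}}.
#' @return logical vector, one entry per frame.
#' @export
isTSLike <- function(geometry, criteria = tsCriteria()) {
  geometry$d < criteria$dMax &
    abs(geometry$thetaAttack - criteria$attackCenter) <= criteria$attackTol &
    abs(geometry$thetaLinear - criteria$linearCenter) <= criteria$linearTol
}

#' Count TS-like frames in a simulation
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param atomMap see \code{\link{ensembleGeometry}}.
#' @param criteria a \code{\link{tsCriteria}}.
#' @return one-row data.frame: \code{simulation_id}, \code{substrate},
#'   \code{ts_frames}, \code{total_frames}.
#' @export
countTSFrames <- function(ensemble, atomMap = NULL,
                          criteria = tsCriteria()) {
  ts <- sum(isTSLike(ensembleGeometry(ensemble, atomMap), criteria))
  data.frame(simulation_id = ensemble@simulationId,
             substrate = ensemble@substrate,
             ts_frames = as.integer(ts),
             total_frames = nFrames(ensemble),
             stringsAsFactors = FALSE)
}

#' Bin simulations into high/low TS-frequency classes
#'
#' Each simulation is assigned to the high bin when its TS-frame count
#' is strictly greater than the threshold (ties go low). The default
#' threshold is the median of the pooled per-simulation counts; the rule
#' is recorded on the returned table.
#'
#' @param recordsA,recordsB data.frames of per-simulation counts (as from
#'   \code{\link{countTSFrames}}) for the two substrates.
#' @param thresholdRule \code{"median"} (pooled median) or \code{"fixed"}.
#' @param threshold numeric threshold when \code{thresholdRule = "fixed"}.
#' @return 2 x 2 integer matrix, rows = substrates, columns =
#'   \code{c("high", "low")}, with attributes \code{threshold} and
#'   \code{thresholdRule}.
#' @export
binSimulations <- function(recordsA, recordsB,
                           thresholdRule = c("median", "fixed"),
                           threshold = NULL) {
  thresholdRule <- match.arg(thresholdRule)
  if (nrow(recordsA) == 0L || nrow(recordsB) == 0L)
    stop("need at least one simulation record per substrate")
  pooled <- c(recordsA$ts_frames, recordsB$ts_frames)
  thr <- switch(thresholdRule,
                median = stats::median(pooled),
                fixed = {
                  if (is.null(threshold))
                    stop("fixed rule needs a threshold")
                  threshold
                })
  tab <- rbind(c(sum(recordsA$ts_frames > thr), sum(recordsA$ts_frames <= thr)),
               c(sum(recordsB$ts_frames > thr), sum(recordsB$ts_frames <= thr)))
  storage.mode(tab) <- "integer"
  dimnames(tab) <- list(c(recordsA$substrate[1L], recordsB$substrate[1L]),
                        c("high", "low"))
  attr(tab, "threshold") <- thr
  attr(tab, "thresholdRule") <- thresholdRule
  tab
}

#' Two-sided Fisher's exact test for a 2 x 2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities,
#' over all tables with the observed margins, of tables no more probable
#' than the observed one. Probabilities are computed in log space from
#' log binomial coefficients, so the test stays exact at any study scale
#' without overflow.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @export
fisherExactTwoSided <- function(table) {
  if (!all(dim(table) == 2L)) stop("need a 2 x 2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  a <- table[1L, 1L]
  r1 <- sum(table[1L, ]); r2 <- sum(table[2L, ])
  c1 <- sum(table[, 1L]); n <- r1 + r2
  if (n == 0L) return(1)
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  logObs <- logp[support == a]
  # relative tolerance guards ties against floating-point noise,
  # matching the conventional two-sided definition
  sum(exp(logp[logp <= logObs + 1e-7]))
}

#' Pooled TS-frequency ratio between substrates
#'
#' Frame-pooled by default: summed TS frames over summed frames per
#' substrate, then the ratio A/B. The mean-of-per-simulation-fractions
#' variant is also available since pooling bases differ between studies.
#'
#' @param recordsA,recordsB per-simulation count tables (substrate A in
#'   the numerator).
#' @param basis \code{"pooled"} or \code{"mean_of_fractions"}.
#' @return list with \code{ratio}, per-substrate frequencies
#'   \code{freqA}, \code{freqB}, the \code{basis}, and \code{infinite}
#'   flag set when the denominator frequency is zero.
#' @export
pooledTSRatio <- function(recordsA, recordsB,
                          basis = c("pooled", "mean_of_fractions")) {
  basis <- match.arg(basis)
  if (sum(recordsA$total_frames) == 0L || sum(recordsB$total_frames) == 0L)
    stop("zero total frames")
  fA <- switch(basis,
               pooled = sum(recordsA$ts_frames) / sum(recordsA$total_frames),
               mean_of_fractions =
                 mean(recordsA$ts_frames / recordsA$total_frames))
  fB <- switch(basis,
               pooled = sum(recordsB$ts_frames) / sum(recordsB$total_frames),
               mean_of_fractions =
                 mean(recordsB$ts_frames / recordsB$total_frames))
  inf <- fB == 0
  list(ratio = if (inf) Inf else fA / fB, freqA = fA, freqB = fB,
       basis = basis, infinite = inf)
}

#' High/low enrichment statistics for two substrates
#'
#' Convenience wrapper: bins the per-simulation counts, runs the exact
#' test and computes both frequency-ratio variants.
#'
#' @inheritParams binSimulations
#' @return list with the contingency \code{table}, \code{threshold},
#'   \code{p}, \code{ratioPooled} and \code{ratioMeanOfFractions}.
#' @export
tsEnrichment <- function(recordsA, recordsB,
                         thresholdRule = c("median", "fixed"),
                         threshold = NULL) {
  tab <- binSimulations(recordsA, recordsB, thresholdRule, threshold)
  list(table = tab,
       threshold = attr(tab, "threshold"),
       thresholdRule = attr(tab, "thresholdRule"),
       p = fisherExactTwoSided(tab),
       ratioPooled = pooledTSRatio(recordsA, recordsB, "pooled"),
       ratioMeanOfFractions = pooledTSRatio(recordsA, recordsB,
                                            "mean_of_fractions"))
}
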