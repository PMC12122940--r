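# Synthetic inputs with planted statistical structure: toy
# enzyme-peptide-cofactor ensembles with known TS-frame and contact
# fractions, duplicate specificity arrays with a planted preference
# matrix, and progress curves obeying the shared-amplitude model.
# Geometry only; no force field, thermostat or solvent.

# Vectorized uniform random rotations (unit quaternion -> matrix rows).
randomQuaternions <- function(n) {
  q <- matrix(stats::rnorm(4L * n), n, 4L)
  q / sqrt(rowSums(q^2))
}

# Apply per-frame rotations (n x 4 quaternions) + translations (n x 3)
# to per-frame points given as length-n coordinate vectors.
rotateTranslate <- function(x, y, z, q, tr) {
  w <- q[, 1L]; a <- q[, 2L]; b <- q[, 3L]; c <- q[, 4L]
  xr <- (1 - 2 * (b^2 + c^2)) * x + 2 * (a * b - w * c) * y +
    2 * (a * c + w * b) * z
  yr <- 2 * (a * b + w * c) * x + (1 - 2 * (a^2 + c^2)) * y +
    2 * (b * c - w * a) * z
  zr <- 2 * (a * c - w * b) * x + 2 * (b * c + w * a) * y +
    (1 - 2 * (a^2 + b^2)) * z
  cbind(xr + tr[, 1L], yr + tr[, 2L], zr + tr[, 3L])
}

#' Planted contact table
#'
#' @param peptide,enzyme residue labels (e.g. \code{"P:R2"},
#'   \code{"E:Y361"}).
#' @param fraction target contact fraction in [0, 1] per pair.
#' @param in_distance atom distance in contact frames, must be < 4.5.
#' @param out_distance atom distance otherwise, must be > 4.5.
#' @return data.frame consumed by \code{\link{makeToyComplexEnsemble}}.
#' @export
contactPlant <- function(peptide, enzyme, fraction, in_distance = 3.5,
                         out_distance = 9) {
  df <- data.frame(peptide = peptide, enzyme = enzyme,
                   fraction = fraction, in_distance = in_distance,
                   out_distance = out_distance, stringsAsFactors = FALSE)
  if (any(df$fraction < 0 | df$fraction > 1))
    stop("contact fractions must lie in [0, 1]")
  if (any(df$in_distance >= 4.5) || any(df$out_distance <= 4.5))
    stop("need in_distance < 4.5 < out_distance")
  df
}

#' Generate a toy enzyme-peptide-cofactor ensemble
#'
#' Builds a minimal atom set: target-lysine Cdelta and Nepsilon, the
#' cofactor methyl carbon and sulfur, plus one heavy atom per planted
#' contact residue. Per frame, with probability \code{tsFraction} the
#' four-atom geometry satisfies all three TS criteria (drawn comfortably
#' inside the bounds); otherwise exactly one randomly chosen criterion
#' is violated by a margin of at least \code{geometryNoise} (degrees;
#' \code{geometryNoise/10} Angstrom for the distance), so no frame ever
#' sits on a criterion boundary. Each planted contact pair is placed at
#' its \code{in_distance} in an independent Bernoulli(fraction) subset
#' of frames and at \code{out_distance} otherwise. A random rigid
#' motion is applied to every frame. Fully reproducible given
#' \code{seed}.
#'
#' @param tsFraction probability of a TS-like frame, in [0, 1].
#' @param nFrames number of frames (>= 1); default 5000, i.e. a 100 ns
#'   run at the 20 ps frame stride.
#' @param geometryNoise violation margin for non-TS frames (degrees).
#' @param contacts optional \code{\link{contactPlant}} table.
#' @param seed integer seed; all randomness flows from it.
#' @param stride frame spacing metadata in ps.
#' @param simulationId,replicateGroup,substrate ensemble metadata.
#' @param targetResno residue number of the target lysine (4 for H3K4,
#'   36 for H3K36).
#' @param criteria \code{\link{tsCriteria}} the construction respects.
#' @param tsPattern optional logical vector of length \code{nFrames}
#'   planting the TS frames deterministically (overrides
#'   \code{tsFraction}).
#' @param contactPattern optional list of logical vectors (one per
#'   contact row) planting contact frames deterministically.
#' @param rotateFrames apply the per-frame rigid motion (default TRUE).
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
makeToyComplexEnsemble <- function(tsFraction, nFrames = 5000L,
                                   geometryNoise = 5, contacts = NULL,
                                   seed = 1L, stride = 20,
                                   simulationId = "sim1",
                                   replicateGroup = "batch1",
                                   substrate = "H3K4",
                                   targetResno = if (substrate == "H3K36") 36L else 4L,
                                   criteria = tsCriteria(),
                                   tsPattern = NULL,
                                   contactPattern = NULL,
                                   rotateFrames = TRUE) {
  if (nFrames < 1L) stop("nFrames must be >= 1")
  if (tsFraction < 0 || tsFraction > 1)
    stop("tsFraction must lie in [0, 1]")
  if (geometryNoise < 0) stop("geometryNoise must be non-negative")
  set.seed(seed)
  nf <- as.integer(nFrames)
  ts <- tsPattern %||% (stats::runif(nf) < tsFraction)
  stopifnot(length(ts) == nf)

  # comfortable interior of the TS region (margin away from every bound)
  dIn <- stats::runif(nf, 0.75 * criteria$dMax, 0.97 * criteria$dMax)
  aIn <- stats::runif(nf, criteria$attackCenter - 0.8 * criteria$attackTol,
                      criteria$attackCenter + 0.8 * criteria$attackTol)
  lIn <- stats::runif(nf, criteria$linearCenter - 0.8 * criteria$linearTol,
                      criteria$linearCenter)
  d <- dIn; ang <- aIn; lin <- lIn

  bad <- which(!ts)
  if (length(bad)) {
    which3 <- sample.int(3L, length(bad), replace = TRUE)
    distMargin <- pmax(0.3, geometryNoise / 10)
    i <- bad[which3 == 1L]
    d[i] <- criteria$dMax + distMargin + stats::runif(length(i), 0, 2)
    i <- bad[which3 == 2L]
    if (length(i)) {
      lowRoom <- criteria$attackCenter - criteria$attackTol -
        geometryNoise - 15
      hiRoom <- 180 - (criteria$attackCenter + criteria$attackTol +
                         geometryNoise + 15)
      side <- if (lowRoom >= 0 && hiRoom >= 0)
        sample(c(-1, 1), length(i), replace = TRUE)
      else if (lowRoom >= 0) rep(-1, length(i)) else rep(1, length(i))
      ang[i] <- criteria$attackCenter +
        side * (criteria$attackTol + geometryNoise +
                  stats::runif(length(i), 0, 15))
    }
    i <- bad[which3 == 3L]
    lin[i] <- criteria$linearCenter -
      (criteria$linearTol + geometryNoise + stats::runif(length(i), 0, 15))
  }

  # base geometry: Nepsilon at origin, methyl C on +z, Cdelta in the xz
  # plane at the attack angle, S continuing the transfer axis
  angR <- ang * pi / 180; linR <- lin * pi / 180
  base <- list(
    CD = cbind(1.52 * sin(angR), 0, 1.52 * cos(angR)),
    NZ = cbind(0, 0, 0)[rep(1L, nf), , drop = FALSE],
    CE = cbind(0, 0, d),
    SD = cbind(1.81 * sin(linR), 0, d - 1.81 * cos(linR)))

  atoms <- data.frame(
    atomId = 1:4,
    atomName = c("CD", "NZ", "CE", "SD"),
    chain = c("P", "P", "X", "X"),
    resname = c("K", "K", "SAM", "SAM"),
    resno = c(targetResno, targetResno, 900L, 900L),
    stringsAsFactors = FALSE)

  if (!is.null(contacts)) {
    for (p in seq_len(nrow(contacts))) {
      inContact <- if (!is.null(contactPattern))
        contactPattern[[p]]
      else stats::runif(nf) < contacts$fraction[p]
      stopifnot(length(inContact) == nf)
      off <- 100 * p
      pep <- parseResidueLabel(contacts$peptide[p])
      enz <- parseResidueLabel(contacts$enzyme[p])
      dist <- ifelse(inContact, contacts$in_distance[p],
                     contacts$out_distance[p])
      base[[paste0("pep", p)]] <- cbind(0, off, 0)[rep(1L, nf), ,
                                                   drop = FALSE]
      base[[paste0("enz", p)]] <- cbind(dist, off, 0)
      atoms <- rbind(atoms, data.frame(
        atomId = c(3L + 2L * p, 4L + 2L * p),
        atomName = ifelse(c(pep$resname, enz$resname) == "G", "CA", "CB"),
        chain = c(pep$chain, enz$chain),
        resname = c(pep$resname, enz$resname),
        resno = c(pep$resno, enz$resno), stringsAsFactors = FALSE))
    }
  }

  na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  if (rotateFrames) {
    q <- randomQuaternions(nf)
    tr <- matrix(stats::runif(3L * nf, -50, 50), nf, 3L)
  } else {
    q <- cbind(1, 0, 0, 0)[rep(1L, nf), , drop = FALSE]
    tr <- matrix(0, nf, 3L)
  }
  for (a in seq_len(na)) {
    b <- base[[a]]
    coords[a, , ] <- t(rotateTranslate(b[, 1L], b[, 2L], b[, 3L], q, tr))
  }
  trajectoryEnsemble(coords, atoms, stride = stride,
                     simulationId = simulationId,
                     replicateGroup = replicateGroup,
                     substrate = substrate)
}

#' Default planted preference weights for a specificity scan
#'
#' A plausible position x residue weight matrix for the two scans:
#' strong readout where the real enzyme discriminates (H3K4: A/T/V at
#' -3, R/K at -2, V/I/L at -1, T/V/K at +1, V at +2; H3K36: mild G at
#' -3, R/G at -2, I/V at -1, V/I/K at +1, P/V at +2), a uniform
#' tolerated baseline elsewhere, and near-zero signal for substitutions
#' of the target lysine itself.
#'
#' @param substrate \code{"H3K4"} or \code{"H3K36"}.
#' @return positive matrix, 18 residues x 9 positions, values in (0, 1].
#' @export
defaultSpotWeights <- function(substrate = c("H3K4", "H3K36")) {
  substrate <- match.arg(substrate)
  tpl <- scanTemplate(substrate)
  w <- matrix(0.25, length(tpl$residues), length(tpl$positions),
              dimnames = list(tpl$residues, tpl$positions))
  setw <- function(pos, res, val) {
    w[res, pos] <<- val
    invisible(NULL)
  }
  if (substrate == "H3K4") {
    setw("-3", c("A", "T", "V"), 0.90)
    setw("-2", c("R", "K"), 0.92)
    setw("-1", c("V", "I", "L"), 0.85); setw("-1", "T", 0.45)
    setw("+1", c("T", "V", "K"), 0.80); setw("+1", "Q", 0.40)
    setw("+2", "V", 0.88); setw("+2", "T", 0.35)
  } else {
    setw("-3", "G", 0.55)
    setw("-2", c("R", "G"), 0.75)
    setw("-1", "I", 0.90); setw("-1", "V", 0.70)
    setw("+1", c("V", "I"), 0.85); setw("+1", "K", 0.65)
    setw("+2", "P", 0.85); setw("+2", "V", 0.80)
  }
  w[, "0"] <- 0.02
  w["K", "0"] <- 0.95       # unsubstituted target column
  w
}

#' Generate replicate specificity arrays with planted preferences
#'
#' Spot intensity = weight(position, residue) + Gaussian(0, noiseSd),
#' clipped at 0 (autoradiography signals are non-negative). Replicates
#' differ only in their noise realization; each replicate draws from its
#' own sub-stream of \code{seed}.
#'
#' @param weights strictly positive residue x position weight matrix,
#'   e.g. \code{\link{defaultSpotWeights}}.
#' @param substrate \code{"H3K4"} or \code{"H3K36"}.
#' @param nReplicates number of replicate arrays (>= 1; arrays are
#'   measured in duplicate by default).
#' @param noiseSd Gaussian noise SD on the weight scale.
#' @param seed integer seed.
#' @return list of raw \linkS4class{SpecificityArray}s.
#' @export
makeSpotReplicates <- function(weights = defaultSpotWeights(substrate),
                               substrate = "H3K4", nReplicates = 2L,
                               noiseSd = 0.05, seed = 1L) {
  if (nReplicates < 1L) stop("nReplicates must be >= 1")
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  lapply(seq_len(nReplicates), function(r) {
    set.seed(subSeed(seed, r))
    noisy <- pmax(weights + stats::rnorm(length(weights), 0, noiseSd), 0)
    dimnames(noisy) <- dimnames(weights)
    specificityArray(noisy, substrate = substrate,
                     replicateId = paste0("rep", r))
  })
}

#' Generate methylation progress curves from the shared model
#'
#' Signals follow Signal = A + B (1 - exp(-k t)) with substrate-specific
#' rates and shared A, B, plus Gaussian noise; one sub-stream of
#' \code{seed} per experiment.
#'
#' @param A baseline signal (default 0.05).
#' @param B amplitude, > 0 (default 1, the wild-type H3K4 scale).
#' @param k4,k36 rates per minute, > 0; defaults 0.15 and 0.15/5.2, the
#'   wild-type initial-rate ratio of 5.2.
#' @param times sampling times in minutes, non-negative.
#' @param noiseSd Gaussian noise SD in signal units.
#' @param seed integer seed.
#' @param nExperiments independent experimental repeats (default 3).
#' @return list with elements \code{H3K4} and \code{H3K36}, each a
#'   \code{\link{kineticSeries}} data.frame over all experiments.
#' @export
makeProgressCurves <- function(A = 0.05, B = 1, k4 = 0.15, k36 = 0.15 / 5.2,
                               times = c(0, 1, 2, 4, 8, 15, 30, 60),
                               noiseSd = 0, seed = 1L, nExperiments = 3L) {
  if (B <= 0) stop("B must be > 0")
  if (k4 <= 0 || k36 <= 0) stop("rates must be > 0")
  if (any(times < 0)) stop("times must be non-negative")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  one <- function(k, substrate) {
    do.call(rbind, lapply(seq_len(nExperiments), function(e) {
      set.seed(subSeed(seed, 100L * e + (substrate == "H3K36")))
      y <- progressSignal(times, A, B, k) +
        stats::rnorm(length(times), 0, noiseSd)
      kineticSeries(times, y, substrate = substrate, experiment = e)
    }))
  }
  list(H3K4 = one(k4, "H3K4"), H3K36 = one(k36, "H3K36"))
}

#' Per-simulation planted TS fractions of the study design
#'
#' Bimodal per-simulation TS-frame fractions for 21 replicate
#' simulations per substrate: the H3K4 complex samples many
#' high-activity runs (14 at 0.14, 7 at 0.010), the H3K36 complex few
#' (4 at 0.10, 17 at 0.006); the pooled frame-weighted expectation ratio
#' is 4.04, the observed 4-fold enrichment of hyperactive states.
#'
#' @return list with numeric vectors \code{H3K4} and \code{H3K36}.
#' @export
studyTSFractions <- function() {
  list(H3K4 = c(rep(0.14, 14L), rep(0.010, 7L)),
       H3K36 = c(rep(0.10, 4L), rep(0.006, 17L)))
}

#' Simulate per-simulation TS counts at study scale
#'
#' Generates 21 toy ensembles per substrate with the
#' \code{\link{studyTSFractions}} planted fractions (batches of 3 runs
#' per equilibration group), counts TS-like frames with the geometric
#' classifier, and returns the per-simulation count records.
#'
#' @param seed integer seed (one sub-stream per simulation).
#' @param nFramesPerSim frames per simulation (default 5000, a 100 ns
#'   run at 20 ps stride).
#' @param criteria \code{\link{tsCriteria}}.
#' @return list with data.frames \code{H3K4} and \code{H3K36} of
#'   per-simulation count records, plus \code{planted} fractions.
#' @export
simulateStudyTSCounts <- function(seed = 1L, nFramesPerSim = 5000L,
                                  criteria = tsCriteria()) {
  fr <- studyTSFractions()
  out <- lapply(names(fr), function(sub) {
    shuffled <- fr[[sub]]
    do.call(rbind, lapply(seq_along(shuffled), function(i) {
      ens <- makeToyComplexEnsemble(
        tsFraction = shuffled[i], nFrames = nFramesPerSim,
        seed = subSeed(seed, 1000L * (sub == "H3K36") + i),
        simulationId = sprintf("%s_run%02d", sub, i),
        replicateGroup = sprintf("%s_batch%d", sub, ceiling(i / 3)),
        substrate = sub, criteria = criteria)
      countTSFrames(ens, criteria = criteria)
    }))
  })
  names(out) <- names(fr)
  out$planted <- fr
  out
}
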