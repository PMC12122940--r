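#' @import methods
NULL

#' TrajectoryEnsemble: coordinate frames with a shared atom table
#'
#' Ordered coordinate frames of one enzyme-peptide-cofactor simulation.
#' All frames share one atom table; coordinates are stored as an
#' atoms x 3 x frames array in Angstrom.
#'
#' @slot coords numeric array, \code{nAtoms x 3 x nFrames}, Angstrom.
#' @slot atoms data.frame with one row per atom: \code{atomId},
#'   \code{atomName}, \code{chain}, \code{resname} (short form),
#'   \code{resno}, \code{element}, \code{residueLabel}.
#' @slot stride time between consecutive frames in ps.
#' @slot simulationId identifier of the simulation/replicate.
#' @slot replicateGroup equilibration batch tag (runs sharing one
#'   equilibration, e.g. batches of 3 production runs).
#' @slot substrate substrate label carried through to downstream counts
#'   (e.g. \code{"H3K4"} or \code{"H3K36"}).
#' @export
setClass("TrajectoryEnsemble",
  slots = c(coords = "array", atoms = "data.frame", stride = "numeric",
            simulationId = "character", replicateGroup = "character",
            substrate = "character"))

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    msg <- c(msg, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1L] != nrow(object@atoms))
      msg <- c(msg, "atom table and coords disagree on atom count")
    if (d[3L] < 1L) msg <- c(msg, "ensemble must contain at least one frame")
    if (!all(is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
  }
  need <- c("atomId", "atomName", "chain", "resname", "resno", "element",
            "residueLabel")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atom table must have columns:",
                        paste(need, collapse = ", ")))
  else if (anyDuplicated(object@atoms$atomId))
    msg <- c(msg, "atomId must be unique")
  if (length(object@stride) != 1L || !is.finite(object@stride) ||
      object@stride <= 0)
    msg <- c(msg, "stride must be a single positive number (ps)")
  if (length(msg)) msg else TRUE
})

#' AtomSelection: heavy-atom selection for one residue
#'
#' @slot residueLabel the residue selected.
#' @slot mode \code{"side_chain_heavy"} or \code{"all_heavy"} (the mode
#'   actually applied; glycine is promoted to \code{"all_heavy"}).
#' @slot atomIds integer atom ids (never hydrogens, never empty).
#' @export
setClass("AtomSelection",
  slots = c(residueLabel = "character", mode = "character",
            atomIds = "integer"))

setValidity("AtomSelection", function(object) {
  if (length(object@atomIds) < 1L) return("empty atom selection")
  if (!object@mode %in% c("side_chain_heavy", "all_heavy"))
    return("mode must be side_chain_heavy or all_heavy")
  TRUE
})

#' ContactProfile: fraction-of-frames residue contact map
#'
#' Peptide residue (rows) x enzyme residue (columns) matrix of contact
#' counts over an ensemble; fractions are counts / nFrames, so every
#' fraction times nFrames is an integer by construction.
#'
#' @slot counts integer matrix of frames in contact, with residue-label
#'   dimnames.
#' @slot nFrames total number of frames scanned.
#' @slot cutoff contact distance cutoff in Angstrom.
#' @export
setClass("ContactProfile",
  slots = c(counts = "matrix", nFrames = "integer", cutoff = "numeric"))

setValidity("ContactProfile", function(object) {
  msg <- character()
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (any(object@counts < 0) || any(object@counts > object@nFrames))
    msg <- c(msg, "counts must lie in [0, nFrames]")
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    msg <- c(msg, "counts must carry residue-label dimnames")
  if (length(msg)) msg else TRUE
})

#' SpecificityArray: one replicate of a specificity-scan SPOT array
#'
#' Intensity grid of a peptide SPOT specificity scan: each position
#' around the target lysine substituted by each of the 18 scanned
#' residues (all proteinogenic amino acids except W and C).
#'
#' @slot intensities numeric matrix, rows = substituted residue letters,
#'   columns = position labels relative to the target K (e.g. "-3".."+5").
#' @slot template template peptide sequence (one-letter).
#' @slot templateStart H3 residue number of the first template position.
#' @slot targetPosition index of the target lysine within the template.
#' @slot replicateId replicate identifier.
#' @slot substrate substrate tag, e.g. "H3K4".
#' @slot normalized TRUE once min-max normalized to the array extrema.
#' @export
setClass("SpecificityArray",
  slots = c(intensities = "matrix", template = "character",
            templateStart = "integer", targetPosition = "integer",
            replicateId = "character", substrate = "character",
            normalized = "logical"))

setValidity("SpecificityArray", function(object) {
  msg <- character()
  x <- object@intensities
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "intensities must have residue rownames and position colnames")
  if (anyNA(x)) msg <- c(msg, "intensity grid must be complete (no NA)")
  else if (any(x < 0)) msg <- c(msg, "intensities must be >= 0")
  if (!is.null(rownames(x)) && !all(rownames(x) %in% SCAN_RESIDUES))
    msg <- c(msg, "rows must be scan residues (18 letters, no W, no C)")
  tp <- object@targetPosition
  if (length(object@template) != 1L || tp < 1L ||
      tp > nchar(object@template) ||
      substr(object@template, tp, tp) != "K")
    msg <- c(msg, "targetPosition must index a K in the template")
  if (length(msg)) msg else TRUE
})

#' SpotProfile: replicate-averaged, normalized array profile
#'
#' @slot mean mean normalized intensities (0-1 scale), residue x position.
#' @slot error per-spot replicate error on the same 0-1 scale
#'   (mean absolute deviation from the replicate mean by default).
#' @slot nReplicates number of replicates averaged.
#' @slot errorType "mad_from_mean" (|a-b|/2 for duplicates) or "range"
#'   (|a-b| for duplicates).
#' @slot substrate substrate tag.
#' @export
setClass("SpotProfile",
  slots = c(mean = "matrix", error = "matrix", nReplicates = "integer",
            errorType = "character", substrate = "character"))

setValidity("SpotProfile", function(object) {
  msg <- character()
  if (!identical(dim(object@mean), dim(object@error)))
    msg <- c(msg, "mean and error grids must have identical shape")
  if (any(object@mean < -1e-12) || any(object@mean > 1 + 1e-12))
    msg <- c(msg, "mean profile must lie on the normalized 0-1 scale")
  if (any(object@error < 0)) msg <- c(msg, "errors must be >= 0")
  if (object@nReplicates < 2L) msg <- c(msg, "at least 2 replicates required")
  if (length(msg)) msg else TRUE
})

#' DiscriminationProfile: per-position residue preference factors
#'
#' Discrimination factor of residue a at position p: the (epsilon-guarded)
#' mean intensity of a relative to the average over all other residues at
#' that position.
#'
#' @slot df positive matrix, residue x position.
#' @slot epsilon additive guard applied on the 0-1 intensity scale.
#' @slot reference tag naming the reference definition used
#'   ("mean_of_others").
#' @export
setClass("DiscriminationProfile",
  slots = c(df = "matrix", epsilon = "numeric", reference = "character"))

setValidity("DiscriminationProfile", function(object) {
  if (any(object@df <= 0)) return("discrimination factors must be > 0")
  TRUE
})

#' SharedFitResult: shared-amplitude two-rate progress-curve fit
#'
#' Joint least-squares fit of Signal = A + B (1 - exp(-k t)) to two
#' substrate time courses with A and B shared, so the ratio of initial
#' rates (B k) equals the rate-constant ratio k_H3K4 / k_H3K36.
#'
#' @slot estimate named numeric: A, B, kH3K4, kH3K36.
#' @slot se named numeric standard errors (Gauss-Newton covariance
#'   approximation at the optimum).
#' @slot cov 4 x 4 covariance matrix of the estimates.
#' @slot ratio k_H3K4 / k_H3K36.
#' @slot ratioSE delta-method standard error of the ratio (includes the
#'   k4-k36 covariance).
#' @slot rss residual sum of squares.
#' @slot nObs number of fitted points.
#' @slot converged optimizer convergence flag.
#' @slot message optimizer diagnostic message.
#' @export
setClass("SharedFitResult",
  slots = c(estimate = "numeric", se = "numeric", cov = "matrix",
            ratio = "numeric", ratioSE = "numeric", rss = "numeric",
            nObs = "integer", converged = "logical", message = "character"))

setValidity("SharedFitResult", function(object) {
  msg <- character()
  need <- c("A", "B", "kH3K4", "kH3K36")
  if (!all(need %in% names(object@estimate)))
    msg <- c(msg, "estimate must name A, B, kH3K4, kH3K36")
  else {
    if (object@estimate[["B"]] <= 0) msg <- c(msg, "B must be > 0")
    if (object@estimate[["kH3K4"]] <= 0 || object@estimate[["kH3K36"]] <= 0)
      msg <- c(msg, "rates must be > 0")
  }
  if (length(msg)) msg else TRUE
})
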