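#' Contact analysis configuration
#'
#' @param cutoff contact distance cutoff in Angstrom; a residue pair is
#'   in contact in a frame iff at least one inter-selection heavy-atom
#'   pair lies strictly below it (default 4.5, the conventional
#'   heavy-atom contact cutoff).
#' @param neighborExclusion sequence-neighbour exclusion: pairs of
#'   residues on the same chain with residue-number difference at most
#'   this value never count (default 1). Inter-chain pairs are never
#'   excluded.
#' @return list of class \code{ContactConfig}.
#' @export
contactConfig <- function(cutoff = 4.5, neighborExclusion = 1L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff,
                 neighborExclusion = as.integer(neighborExclusion)),
            class = "ContactConfig")
}

pairExcluded <- function(ensemble, selA, selB, config) {
  at <- atomTable(ensemble)
  a <- at[match(selA@atomIds[1L], at$atomId), ]
  b <- at[match(selB@atomIds[1L], at$atomId), ]
  identical(a$chain, b$chain) &&
    abs(a$resno - b$resno) <= config$neighborExclusion
}

# Logical vector over frames: any inter-selection atom pair < cutoff.
contactFrames <- function(ensemble, selA, selB, config = contactConfig()) {
  if (length(intersect(selA@atomIds, selB@atomIds)) > 0L)
    stop("overlapping atom selections")
  if (pairExcluded(ensemble, selA, selB, config))
    return(rep(FALSE, nFrames(ensemble)))
  ra <- selectionRows(ensemble, selA)
  rb <- selectionRows(ensemble, selB)
  cut2 <- config$cutoff^2
  co <- ensemble@coords
  hit <- rep(FALSE, nFrames(ensemble))
  for (i in ra) {
    xi <- co[i, 1L, ]; yi <- co[i, 2L, ]; zi <- co[i, 3L, ]
    for (j in rb) {
      d2 <- (xi - co[j, 1L, ])^2 + (yi - co[j, 2L, ])^2 +
        (zi - co[j, 3L, ])^2
      hit <- hit | (d2 < cut2)
    }
    if (all(hit)) break
  }
  hit
}

#' Are two residues in contact in one frame?
#'
#' True iff at least one heavy-atom pair between the two selections lies
#' strictly below the cutoff; a pair at exactly the cutoff is not a
#' contact. Sequence-neighbour pairs on the same chain never count.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param frame 1-based frame index.
#' @param selA,selB disjoint \linkS4class{AtomSelection}s.
#' @param config a \code{\link{contactConfig}}.
#' @return logical.
#' @export
residuesInContact <- function(ensemble, frame, selA, selB,
                              config = contactConfig()) {
  if (length(intersect(selA@atomIds, selB@atomIds)) > 0L)
    stop("overlapping atom selections")
  if (pairExcluded(ensemble, selA, selB, config)) return(FALSE)
  xyz <- frameCoords(ensemble, frame)
  a <- xyz[selectionRows(ensemble, selA), , drop = FALSE]
  b <- xyz[selectionRows(ensemble, selB), , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  any(d2 < config$cutoff^2)
}

#' Fraction-of-frames contact map between peptide and enzyme residues
#'
#' For every (peptide residue, enzyme residue) pair, the proportion of
#' frames in which the two residues are in contact. Peptide selections
#' use side-chain heavy atoms with automatic promotion of glycine to all
#' (heavy) atoms; enzyme selections use side-chain heavy atoms as well
#' unless \code{enzymeMode} says otherwise.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param peptideResidues,enzymeResidues residue labels (rows/columns of
#'   the map, ordered by residue number).
#' @param config a \code{\link{contactConfig}}.
#' @param peptideMode,enzymeMode selection modes passed to
#'   \code{\link{selectAtoms}}.
#' @return a \linkS4class{ContactProfile}.
#' @export
contactFractionMap <- function(ensemble, peptideResidues, enzymeResidues,
                               config = contactConfig(),
                               peptideMode = "side_chain_heavy",
                               enzymeMode = "side_chain_heavy") {
  if (length(peptideResidues) == 0L || length(enzymeResidues) == 0L)
    stop("empty residue list")
  ordByResno <- function(labels) {
    labels[order(parseResidueLabel(labels)$resno)]
  }
  peptideResidues <- ordByResno(peptideResidues)
  enzymeResidues <- ordByResno(enzymeResidues)
  selP <- lapply(peptideResidues, selectAtoms, ensemble = ensemble,
                 mode = peptideMode)
  selE <- lapply(enzymeResidues, selectAtoms, ensemble = ensemble,
                 mode = enzymeMode)
  counts <- matrix(0L, length(peptideResidues), length(enzymeResidues),
                   dimnames = list(peptideResidues, enzymeResidues))
  for (i in seq_along(selP))
    for (j in seq_along(selE))
      counts[i, j] <- sum(contactFrames(ensemble, selP[[i]], selE[[j]],
                                        config))
  new("ContactProfile", counts = counts, nFrames = nFrames(ensemble),
      cutoff = config$cutoff)
}

#' @describeIn contactFractions fractions = counts / nFrames
#' @export
setMethod("contactFractions", "ContactProfile",
          function(x) x@counts / x@nFrames)

#' @describeIn contactCounts integer contact counts
#' @export
setMethod("contactCounts", "ContactProfile", function(x) x@counts)

#' @describeIn residueLabels row (peptide) and column (enzyme) labels of
#'   a contact profile
#' @param side \code{"peptide"} (rows) or \code{"enzyme"} (columns).
#' @export
setMethod("residueLabels", "ContactProfile",
          function(x, side = c("peptide", "enzyme"), ...) {
            side <- match.arg(side)
            if (side == "peptide") rownames(x@counts) else colnames(x@counts)
          })

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile: %d peptide x %d enzyme residues over %d frames (cutoff %g A)\n",
              nrow(object@counts), ncol(object@counts), object@nFrames,
              object@cutoff))
  print(round(contactFractions(object), 2))
})

#' Pool contact profiles over replicate simulations
#'
#' Frame-weighted pooling: summed contact counts over summed frames, not
#' a mean of per-run fractions (a per-run mean is available from
#' \code{contactFractions} applied to each profile).
#'
#' @param profiles list of \linkS4class{ContactProfile}s with identical
#'   row and column labels.
#' @return pooled \linkS4class{ContactProfile}.
#' @export
mergeProfiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to merge")
  ref <- profiles[[1L]]
  for (p in profiles[-1L]) {
    if (!identical(dimnames(p@counts), dimnames(ref@counts)))
      stop("profiles have mismatched residue labels")
    if (!identical(p@cutoff, ref@cutoff))
      stop("profiles computed with different cutoffs")
  }
  counts <- Reduce(`+`, lapply(profiles, contactCounts))
  new("ContactProfile", counts = counts,
      nFrames = sum(vapply(profiles, function(p) p@nFrames, 1L)),
      cutoff = ref@cutoff)
}

#' Export a contact profile
#'
#' Writes either the wide residue x residue fraction matrix or a long
#' table (peptide_residue, enzyme_residue, fraction, n_frames).
#' Fractions are written at full precision; rounding for display is the
#' reader's choice.
#'
#' @param profile a \linkS4class{ContactProfile}.
#' @param path output file.
#' @param layout \code{"wide"} or \code{"long"}.
#' @return \code{path}, invisibly.
#' @export
writeContactProfile <- function(profile, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  fr <- contactFractions(profile)
  if (layout == "wide") {
    utils::write.table(data.frame(peptide_residue = rownames(fr), fr,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    long <- data.frame(
      peptide_residue = rep(rownames(fr), times = ncol(fr)),
      enzyme_residue = rep(colnames(fr), each = nrow(fr)),
      fraction = as.vector(fr),
      n_frames = profile@nFrames)
    utils::write.table(long, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
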